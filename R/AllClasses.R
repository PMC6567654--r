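#' OneHotMatrix: binary category-by-position encoding of a DNA sequence
#'
#' A binary matrix whose rows are categories (k-mers for the order-k schemes,
#' ordered base-pair substitutions for the mismatch scheme) and whose columns
#' are sequence positions, with position 1 (the 5'-most base of the TTTN PAM)
#' leftmost. For an order-k scheme every column carries exactly one 1; for the
#' mismatch scheme a column is all zero at matched positions and carries one 1
#' at mismatched positions, so the matrix total equals the Hamming distance of
#' the guide/target pair.
#'
#' @slot scheme one of `"order1"`, `"order2"`, `"order3"`, `"mismatch"`.
#'
#' @seealso [encodeOrderK()], [encodeMismatchPair()], [permuteRows()]
#' @export
setClass("OneHotMatrix",
         contains = "matrix",
         representation(scheme = "character"))

setValidity("OneHotMatrix", function(object) {
  m <- object@.Data
  if (!all(m %in% c(0, 1)))
    return("entries must all be 0 or 1")
  if (length(object@scheme) != 1L ||
      !object@scheme %in% c("order1", "order2", "order3", "mismatch"))
    return("scheme must be one of order1/order2/order3/mismatch")
  if (object@scheme == "mismatch") {
    if (nrow(m) != 12L)
      return("mismatch scheme requires 12 rows")
    if (!all(colSums(m) %in% c(0, 1)))
      return("mismatch columns must sum to 0 or 1")
  } else {
    k <- as.integer(sub("order", "", object@scheme))
    if (nrow(m) != 4L^k)
      return(sprintf("order-%d scheme requires %d rows", k, 4L^k))
    if (!all(colSums(m) == 1))
      return("order-k columns must each sum to exactly 1")
  }
  TRUE
})

#' @describeIn OneHotMatrix-class compact display
#' @param object a `OneHotMatrix`.
#' @export
setMethod("show", "OneHotMatrix", function(object) {
  cat(sprintf("OneHotMatrix (%s): %d categories x %d positions, total = %d\n",
              object@scheme, nrow(object), ncol(object), sum(object@.Data)))
})

#' NetSpec: architecture and optimizer hyperparameters of a classifier
#'
#' Describes one convolution + sum-pooling + dense stage ending in a two-unit
#' softmax head. Derived shapes (valid-convolution output, truncating pooled
#' shape, flatten size) are computed, never stored, so the printed identities
#' (e.g. 50 maps of 12 x 22 pooled to 6 x 11, flatten 3300) are arithmetic
#' consequences of the slots.
#'
#' @slot inputShape integer(2): rows, columns of the input matrix.
#' @slot nFilters number of convolution filters.
#' @slot kernel integer(2): filter height, width (valid convolution).
#' @slot pool integer(2): pooling block height, width (non-overlapping sums;
#'   trailing odd rows/columns are dropped).
#' @slot denseUnits width of the fully connected layer.
#' @slot learningRate base learning rate of gradient descent (default 0.005).
#' @slot momentum momentum coefficient (default 0.9).
#' @slot batchSize mini-batch size (default 40).
#' @slot epochs default number of training epochs.
#'
#' @seealso [netSpec()], [convShape()], [flattenSize()]
#' @export
setClass("NetSpec",
         representation(inputShape = "integer",
                        nFilters = "integer",
                        kernel = "integer",
                        pool = "integer",
                        denseUnits = "integer",
                        learningRate = "numeric",
                        momentum = "numeric",
                        batchSize = "integer",
                        epochs = "integer"))

setValidity("NetSpec", function(object) {
  if (length(object@inputShape) != 2L || any(object@inputShape < 1L))
    return("inputShape must be two positive integers")
  if (length(object@kernel) != 2L || any(object@kernel < 1L))
    return("kernel must be two positive integers")
  if (any(object@kernel > object@inputShape))
    return("kernel must fit within the input (kh <= rows, kw <= cols)")
  if (length(object@pool) != 2L || any(object@pool < 1L))
    return("pool must be two positive integers")
  cs <- object@inputShape - object@kernel + 1L
  if (any(cs %/% object@pool < 1L))
    return("pooling must leave at least one cell per feature map")
  if (object@nFilters < 1L || object@denseUnits < 1L)
    return("nFilters and denseUnits must be positive")
  if (object@learningRate <= 0 || object@momentum < 0 || object@momentum >= 1)
    return("learningRate must be > 0 and momentum in [0, 1)")
  if (object@batchSize < 1L || object@epochs < 0L)
    return("batchSize must be >= 1 and epochs >= 0")
  TRUE
})

#' @describeIn NetSpec-class compact display with derived shapes
#' @param object a `NetSpec`.
#' @export
setMethod("show", "NetSpec", function(object) {
  cs <- convShape(object); ps <- pooledShape(object)
  cat(sprintf(paste0("NetSpec: input %dx%d | %d filters %dx%d -> maps %dx%d",
                     " | pool %dx%d -> %dx%d | flatten %d | dense %d | 2-way",
                     " softmax\n  lr %.4g, momentum %.2g, batch %d, epochs %d\n"),
              object@inputShape[1], object@inputShape[2], object@nFilters,
              object@kernel[1], object@kernel[2], cs[1], cs[2],
              object@pool[1], object@pool[2], ps[1], ps[2],
              flattenSize(object), object@denseUnits,
              object@learningRate, object@momentum, object@batchSize,
              object@epochs))
})

#' Cpf1Classifier: a (possibly trained) convolutional sequence classifier
#'
#' Holds the architecture ([NetSpec-class]), the convolution filter bank,
#' the two dense layers, and the decision threshold applied to the
#' positive-class score. Freshly built classifiers have a zero-initialized
#' output layer, so they score every input exactly 0.5 until trained.
#'
#' @slot spec the [NetSpec-class].
#' @slot convW matrix (kh*kw) x nFilters: filter bank, kernel cells in
#'   column-major order.
#' @slot convB numeric(nFilters): convolution biases.
#' @slot W1,b1 dense layer flatten -> denseUnits.
#' @slot W2,b2 output layer denseUnits -> 2 class scores.
#' @slot threshold positive-class score cutoff (default 0.5).
#' @slot trained logical flag.
#' @slot seed integer seed used for weight initialization.
#' @slot history numeric vector of per-epoch mean training losses.
#'
#' @seealso [buildOnTargetNet()], [buildOffTargetNet()], [trainClassifier()]
#' @export
setClass("Cpf1Classifier",
         representation(spec = "NetSpec",
                        convW = "matrix", convB = "numeric",
                        W1 = "matrix", b1 = "numeric",
                        W2 = "matrix", b2 = "numeric",
                        threshold = "numeric",
                        trained = "logical",
                        seed = "integer",
                        history = "numeric"))

setValidity("Cpf1Classifier", function(object) {
  s <- object@spec
  kk <- prod(s@kernel)
  if (!identical(dim(object@convW), c(as.integer(kk), s@nFilters)))
    return("convW must be (kh*kw) x nFilters")
  if (length(object@convB) != s@nFilters)
    return("convB length must equal nFilters")
  if (!identical(dim(object@W1), c(flattenSize(s), s@denseUnits)))
    return("W1 must be flattenSize x denseUnits")
  if (length(object@b1) != s@denseUnits)
    return("b1 length must equal denseUnits")
  if (!identical(dim(object@W2), c(s@denseUnits, 2L)))
    return("W2 must be denseUnits x 2")
  if (length(object@b2) != 2L)
    return("b2 must have length 2")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  TRUE
})

#' @describeIn Cpf1Classifier-class compact display
#' @param object a `Cpf1Classifier`.
#' @export
setMethod("show", "Cpf1Classifier", function(object) {
  cat(sprintf("Cpf1Classifier (%s, threshold %.2f, seed %d)\n",
              if (object@trained) "trained" else "untrained",
              object@threshold, object@seed))
  show(object@spec)
})

#' LibraryDesign: result of the end-to-end guide library pipeline
#'
#' @slot guides [GenomicRanges::GRanges] of the selected guides, ranked by
#'   (fewest predicted high-activity off-target sites, highest activity,
#'   leftmost coordinate), with metadata columns `sequence`, `gcFraction`,
#'   `hasPolyT`, `activity`, `nHighOffTargets`, `specificity`.
#' @slot offTargets [GenomicRanges::GRangesList], one element per guide,
#'   holding the enumerated off-target hits and their predicted scores.
#' @slot params list of the pipeline parameters actually used.
#' @slot shortfall TRUE when fewer candidates survived than were requested.
#'
#' @seealso [designLibrary()]
#' @export
setClass("LibraryDesign",
         representation(guides = "GRanges",
                        offTargets = "GRangesList",
                        params = "list",
                        shortfall = "logical"))

#' @describeIn LibraryDesign-class compact display
#' @param object a `LibraryDesign`.
#' @export
setMethod("show", "LibraryDesign", function(object) {
  cat(sprintf("LibraryDesign: %d guide(s)%s\n", length(object@guides),
              if (object@shortfall) " [fewer than requested survived]" else ""))
  if (length(object@guides)) {
    df <- as.data.frame(object@guides)
    print(head(df[, c("seqnames", "start", "end", "strand",
                      "activity", "nHighOffTargets")], 10))
  }
})
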