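#' Construct a network specification
#'
#' @param inputShape integer(2): input matrix rows, columns.
#' @param nFilters number of convolution filters.
#' @param kernel integer(2): filter shape (valid convolution, no padding).
#' @param pool integer(2): sum-pooling block; trailing odd rows/columns of a
#'   feature map are dropped.
#' @param denseUnits fully connected layer width.
#' @param learningRate,momentum,batchSize optimizer settings; the defaults
#'   (0.005, 0.9, 40) are the standard values used throughout.
#' @param epochs default training epochs.
#' @return a [NetSpec-class].
#' @export
netSpec <- function(inputShape, nFilters, kernel, pool = c(2L, 2L),
                    denseUnits, learningRate = 0.005, momentum = 0.9,
                    batchSize = 40L, epochs = 100L) {
  new("NetSpec",
      inputShape = as.integer(inputShape), nFilters = as.integer(nFilters),
      kernel = as.integer(kernel), pool = as.integer(pool),
      denseUnits = as.integer(denseUnits), learningRate = learningRate,
      momentum = momentum, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs))
}

#' Derived layer shapes
#'
#' Valid convolution of an R x C input with a kh x kw kernel yields maps of
#' (R-kh+1) x (C-kw+1); non-overlapping ph x pw sum pooling with truncation
#' yields floor divisions; the flatten layer concatenates all pooled maps.
#' These identities are computed from the spec, never stored.
#'
#' @param spec a [NetSpec-class].
#' @return `convShape`/`pooledShape`: integer(2); `flattenSize`: integer.
#' @export
convShape <- function(spec) spec@inputShape - spec@kernel + 1L

#' @rdname convShape
#' @export
pooledShape <- function(spec) convShape(spec) %/% spec@pool

#' @rdname convShape
#' @export
flattenSize <- function(spec) {
  ps <- pooledShape(spec)
  spec@nFilters * ps[1] * ps[2]
}

## ---------------------------------------------------------------------------
## Geometry caches: index vectors that turn convolution into one GEMM
## (im2col), pooling into a few vectorized adds, and flattening into a
## column permutation. All positions below are column-major internally;
## the public flatten order is map-major with row-major positions within a
## map (see flattenReceptiveField), hence the permutation.

netGeometry <- function(spec) {
  rows <- spec@inputShape[1]; cols <- spec@inputShape[2]
  kh <- spec@kernel[1]; kw <- spec@kernel[2]
  outR <- rows - kh + 1L; outC <- cols - kw + 1L
  npos <- outR * outC
  ## idx[p, q]: linear index into an input image (column-major) of kernel
  ## cell q when the kernel's top-left corner sits at output position p
  ## (p column-major over (outR, outC), q column-major over (kh, kw)).
  r0 <- rep(seq_len(outR), times = outC)
  c0 <- rep(seq_len(outC), each = outR)
  ki <- rep(seq_len(kh), times = kw)
  kj <- rep(seq_len(kw), each = kh)
  idx <- outer(r0 - 1L, ki, `+`) + (outer(c0 - 2L, kj, `+`)) * rows
  ph <- spec@pool[1]; pw <- spec@pool[2]
  pr <- outR %/% ph; pc <- outC %/% pw
  ppp <- pr * pc
  ## poolMembers[[t]]: for pooled positions (column-major over (pr, pc)),
  ## the conv-map position of the t-th cell of each pooling block.
  pr0 <- rep(seq_len(pr), times = pc)
  pc0 <- rep(seq_len(pc), each = pr)
  poolMembers <- vector("list", ph * pw)
  t <- 0L
  for (j in seq_len(pw)) for (i in seq_len(ph)) {
    t <- t + 1L
    poolMembers[[t]] <- (ph * (pr0 - 1L) + i) + (pw * (pc0 - 1L) + j - 1L) * outR
  }
  ## flattenPerm[n]: internal column (pos + ppp*(map-1), pos column-major)
  ## feeding public flatten neuron n (map-major, row-major positions).
  nmap <- rep(seq_len(spec@nFilters), each = ppp)
  wpos <- rep(seq_len(ppp), times = spec@nFilters)   # row-major within map
  rr <- (wpos - 1L) %/% pc + 1L
  cc <- (wpos - 1L) %% pc + 1L
  flattenPerm <- (nmap - 1L) * ppp + (cc - 1L) * pr + rr
  ## poolParent[p]: pooled cell fed by conv position p, or ppp+1 when p
  ## falls in a truncated trailing row/column (used as a zero sink when
  ## scattering gradients back through the sum pooling).
  pAll <- seq_len(npos)
  rA <- (pAll - 1L) %% outR + 1L
  cA <- (pAll - 1L) %/% outR + 1L
  inPool <- rA <= pr * ph & cA <= pc * pw
  poolParent <- ifelse(inPool,
                       (rA - 1L) %/% ph + 1L + (((cA - 1L) %/% pw)) * pr,
                       ppp + 1L)
  list(rows = rows, cols = cols, outR = outR, outC = outC, npos = npos,
       kk = kh * kw, idx = idx, idxVec = as.vector(idx),
       pr = pr, pc = pc, ppp = ppp,
       poolMembers = poolMembers, poolParent = poolParent,
       flattenPerm = flattenPerm,
       invFlattenPerm = order(flattenPerm))
}

## Coerce a list of OneHotMatrix/matrix inputs (or an n x (rows*cols) matrix)
## into the internal n x (rows*cols) design matrix (images column-major).
stackInputs <- function(X, spec) {
  rows <- spec@inputShape[1]; cols <- spec@inputShape[2]
  if (is.matrix(X) && !is(X, "OneHotMatrix")) {
    if (ncol(X) != rows * cols)
      stop("input matrix must have rows*cols columns")
    return(X)
  }
  if (is(X, "OneHotMatrix")) X <- list(X)
  stopifnot(is.list(X), length(X) >= 1L)
  bad <- which(!vapply(X, function(m)
    is.matrix(m) && nrow(m) == rows && ncol(m) == cols, logical(1)))[1]
  if (!is.na(bad))
    stop(sprintf("input %d does not match the spec's %d x %d input shape",
                 bad, rows, cols))
  t(vapply(X, function(m) as.vector(if (is(m, "OneHotMatrix")) m@.Data else m),
           numeric(rows * cols)))
}

#' Valid 2-D convolution of an input with a filter bank
#'
#' Linear cross-correlation without padding (each filter slides over every
#' fully contained window), plus a per-filter bias, followed by ReLU. A
#' 16 x 26 input convolved with 5 x 5 filters gives 12 x 22 feature maps; a
#' 12 x 27 input with 7 x 7 filters gives 6 x 21 maps.
#'
#' @param input numeric matrix (one input image).
#' @param filters array kh x kw x nFilters, or a (kh*kw) x nFilters matrix of
#'   column-major-vectorized kernels.
#' @param bias numeric(nFilters), default all zero.
#' @param relu apply the rectifier (default TRUE).
#' @return array (R-kh+1) x (C-kw+1) x nFilters of feature maps.
#' @export
convValid <- function(input, filters, bias = NULL, relu = TRUE) {
  stopifnot(is.matrix(input))
  if (is.array(filters) && length(dim(filters)) == 3L) {
    kh <- dim(filters)[1]; kw <- dim(filters)[2]; nf <- dim(filters)[3]
    filters <- matrix(filters, nrow = kh * kw, ncol = nf)
  } else {
    stopifnot(is.matrix(filters))
    nf <- ncol(filters)
    stop2 <- function() stop("cannot infer kernel shape from a flat filter ",
                             "matrix; pass a kh x kw x nFilters array")
    stop2i <- sqrt(nrow(filters))
    if (stop2i != round(stop2i)) stop2()
    kh <- kw <- as.integer(stop2i)
  }
  if (kh > nrow(input) || kw > ncol(input))
    stop(sprintf("kernel %dx%d larger than input %dx%d",
                 kh, kw, nrow(input), ncol(input)))
  if (is.null(bias)) bias <- numeric(nf)
  spec <- netSpec(dim(input), nf, c(kh, kw), c(1L, 1L), 1L)
  g <- netGeometry(spec)
  P <- matrix(input[g$idx], nrow = g$npos, ncol = g$kk)
  conv <- sweep(P %*% filters, 2L, bias, `+`)
  if (relu) conv[conv < 0] <- 0
  array(conv, dim = c(g$outR, g$outC, nf))
}

#' Non-overlapping sum pooling of a feature map
#'
#' Sums ph x pw blocks; trailing rows/columns that do not fill a block are
#' dropped (floor division), so a 12 x 22 map pools to 6 x 11 and a 6 x 21
#' map to 3 x 10.
#'
#' @param map numeric matrix (one feature map).
#' @param pool integer(2): block shape, default 2 x 2.
#' @return pooled matrix of shape `floor(dim(map)/pool)`.
#' @export
sumPool <- function(map, pool = c(2L, 2L)) {
  stopifnot(is.matrix(map), length(pool) == 2L, all(pool >= 1L))
  pr <- nrow(map) %/% pool[1]; pc <- ncol(map) %/% pool[2]
  if (pr < 1L || pc < 1L) stop("map too small for the pooling block")
  out <- matrix(0, pr, pc)
  for (i in seq_len(pool[1])) for (j in seq_len(pool[2]))
    out <- out + map[seq(i, by = pool[1], length.out = pr),
                     seq(j, by = pool[2], length.out = pc), drop = FALSE]
  out
}

## ---------------------------------------------------------------------------
## Batched forward pass (all layers as GEMMs on an n x D design matrix).

## Returns list(F = flatten activations n x flattenSize, and when
## keep = TRUE also convPre (n*npos x nf) needed for backprop).
forwardFlattenCore <- function(Xmat, clf, g, keep = FALSE) {
  n <- nrow(Xmat)
  P <- Xmat[, g$idxVec, drop = FALSE]               # n x (npos*kk)
  dim(P) <- c(n * g$npos, g$kk)
  convPre <- P %*% clf@convW                        # (n*npos) x nf
  convPre <- convPre + rep(clf@convB, each = nrow(convPre))
  conv <- convPre
  conv[conv < 0] <- 0
  dim(conv) <- c(n, g$npos, ncol(conv))
  pooled <- conv[, g$poolMembers[[1]], , drop = FALSE]
  for (t in seq_along(g$poolMembers)[-1])
    pooled <- pooled + conv[, g$poolMembers[[t]], , drop = FALSE]
  dim(pooled) <- c(n, g$ppp * dim(pooled)[3])
  F <- pooled[, g$flattenPerm, drop = FALSE]
  out <- list(F = F, P = if (keep) P, convPre = if (keep) convPre)
  out
}

## Dense head on flatten activations; returns positive-class probabilities
## and, when keep = TRUE, intermediates for backprop.
forwardHead <- function(F, clf, keep = FALSE) {
  Z1 <- F %*% clf@W1
  Z1 <- Z1 + rep(clf@b1, each = nrow(Z1))
  H <- Z1; H[H < 0] <- 0
  Z2 <- H %*% clf@W2
  Z2 <- Z2 + rep(clf@b2, each = nrow(Z2))
  ## numerically stable row softmax over 2 classes
  mx <- pmax(Z2[, 1], Z2[, 2])
  e1 <- exp(Z2[, 1] - mx); e2 <- exp(Z2[, 2] - mx)
  p <- e2 / (e1 + e2)
  list(p = p, Z1 = if (keep) Z1, H = if (keep) H)
}

#' Flatten-layer activations for a batch of inputs
#'
#' Runs the convolution, ReLU, sum pooling and flattening stages only.
#' Neuron order is map-major with row-major positions within each map,
#' matching [flattenReceptiveField()].
#'
#' @param clf a [Cpf1Classifier-class].
#' @param X list of [OneHotMatrix-class]/matrix inputs.
#' @return numeric matrix n x flattenSize.
#' @export
flattenActivations <- function(clf, X) {
  g <- netGeometry(clf@spec)
  forwardFlattenCore(stackInputs(X, clf@spec), clf, g)$F
}

## ---------------------------------------------------------------------------

buildNet <- function(spec, seed) {
  kk <- prod(spec@kernel)
  fs <- flattenSize(spec)
  ## shape identities asserted at build time, computed not hard-coded
  stopifnot(fs == spec@nFilters * prod((spec@inputShape - spec@kernel + 1L)
                                       %/% spec@pool))
  w <- withSeed(seed, list(
    convW = matrix(runif(kk * spec@nFilters, -0.05, 0.05), kk, spec@nFilters),
    W1 = matrix(runif(fs * spec@denseUnits, -1, 1) *
                  sqrt(6 / (fs + spec@denseUnits)), fs, spec@denseUnits)))
  new("Cpf1Classifier", spec = spec,
      convW = w$convW, convB = numeric(spec@nFilters),
      W1 = w$W1, b1 = numeric(spec@denseUnits),
      ## zero-initialized output layer: untrained nets score exactly 0.5
      W2 = matrix(0, spec@denseUnits, 2L), b2 = numeric(2L),
      threshold = 0.5, trained = FALSE, seed = as.integer(seed),
      history = numeric(0))
}

#' Build the on-target activity classifier
#'
#' Architecture for 27-nt matched targets: order-2 one-hot input (16 x 26),
#' 50 filters of 5 x 5 (valid) giving 12 x 22 maps, 2 x 2 sum pooling to
#' 6 x 11, flatten 3300, dense 650, 2-way softmax. `order = 1` swaps in the
#' 4 x 27 input with 4 x 1 convolution and 1 x 2 pooling; `order = 3` the
#' 64 x 25 input with the same 5 x 5 / 2 x 2 stage.
#'
#' @param seed integer seed for weight initialization.
#' @param order one-hot encoding order of the inputs (default 2).
#' @param L input sequence length in nt (default 27; 40 for context-extended
#'   inputs).
#' @return an untrained [Cpf1Classifier-class].
#' @export
buildOnTargetNet <- function(seed = 1L, order = 2L, L = 27L) {
  order <- as.integer(order)
  stopifnot(order %in% 1:3, L >= 27L)
  spec <- switch(order,
    netSpec(c(4L, L), 50L, c(4L, 1L), c(1L, 2L), 650L),
    netSpec(c(16L, L - 1L), 50L, c(5L, 5L), c(2L, 2L), 650L),
    netSpec(c(64L, L - 2L), 50L, c(5L, 5L), c(2L, 2L), 650L))
  buildNet(spec, seed)
}

#' Build the off-target specificity classifier
#'
#' Architecture for guide/target mismatch pairs: 12 x 27 mismatch one-hot
#' input, 35 filters of 7 x 7 (valid) giving 6 x 21 maps, 2 x 2 sum pooling
#' to 3 x 10, flatten 1050, dense 300, 2-way softmax.
#'
#' @param seed integer seed for weight initialization.
#' @return an untrained [Cpf1Classifier-class].
#' @export
buildOffTargetNet <- function(seed = 1L) {
  buildNet(netSpec(c(12L, 27L), 35L, c(7L, 7L), c(2L, 2L), 300L), seed)
}

#' Train a classifier by mini-batch gradient descent with momentum
#'
#' Minimizes the two-class softmax cross-entropy with seeded mini-batch SGD
#' (base learning rate 0.005, momentum 0.9, batch size 40 by default, from
#' the spec). Training is deterministic given the data order, seed and epoch
#' count; `epochs = 0` returns the classifier unchanged apart from the
#' `trained` flag.
#'
#' @param clf a [Cpf1Classifier-class] (weights are taken as the starting
#'   point, so training can be resumed).
#' @param X list of [OneHotMatrix-class]/matrix inputs matching the spec's
#'   input shape.
#' @param y binary labels (0/1), both classes present.
#' @param epochs training epochs; defaults to the spec's value.
#' @param seed integer seed driving batch shuffling.
#' @param engine `"compiled"` (RcppArmadillo core, the default) or
#'   `"reference"` (the pure-R implementation of the same algebra; slower,
#'   kept as an executable specification and cross-check).
#' @return a trained [Cpf1Classifier-class] with per-epoch mean losses in
#'   `@history`.
#' @export
trainClassifier <- function(clf, X, y, epochs = NULL, seed = 1L,
                            engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is(clf, "Cpf1Classifier"))
  spec <- clf@spec
  if (is.null(epochs)) epochs <- spec@epochs
  stopifnot(isWholeNumber(epochs), epochs >= 0)
  Xmat <- stackInputs(X, spec)
  y <- as.integer(y)
  if (length(y) != nrow(Xmat)) stop("length(y) must match the number of inputs")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training requires at least one sample of each class")
  g <- netGeometry(spec)
  n <- nrow(Xmat)
  lr <- spec@learningRate; mom <- spec@momentum; bs <- spec@batchSize
  W <- list(convW = clf@convW, convB = clf@convB, W1 = clf@W1, b1 = clf@b1,
            W2 = clf@W2, b2 = clf@b2)
  V <- lapply(W, function(w) w * 0)
  nf <- spec@nFilters
  history <- numeric(epochs)
  ## epoch shuffles drawn up front so both engines consume the same stream
  orders <- if (epochs > 0)
    withSeed(seed, vapply(seq_len(epochs), function(e) sample.int(n),
                          integer(n)))
  else matrix(integer(0), n, 0)
  if (epochs > 0 && engine == "compiled") {
    members <- do.call(cbind, g$poolMembers)
    res <- .cppTrain(Xmat, y, W$convW, W$convB, W$W1, W$b1, W$W2, W$b2,
                     g$idx, members, g$flattenPerm,
                     lr, mom, bs, orders)
    W <- list(convW = res$convW, convB = as.numeric(res$convB),
              W1 = res$W1, b1 = as.numeric(res$b1),
              W2 = res$W2, b2 = as.numeric(res$b2))
    history <- as.numeric(res$history)
  } else if (epochs > 0) {
    ## pure-R reference path
    ## im2col of the whole dataset, computed once: row (i - 1) * npos + p
    ## holds the kernel window at output position p of sample i.
    Pfull <- Xmat[, g$idxVec, drop = FALSE]         # n x (npos*kk)
    dim(Pfull) <- NULL
    Pfull <- matrix(Pfull, nrow = n * g$npos, ncol = g$kk,
                    byrow = FALSE,
                    dimnames = NULL)                # (sample fastest, pos, k)
    ## reorder rows so each sample's positions are contiguous (pos fastest)
    rowMap <- as.vector(outer((seq_len(g$npos) - 1L) * n, seq_len(n), `+`))
    Pfull <- Pfull[rowMap, , drop = FALSE]
    for (ep in seq_len(epochs)) {
      ord <- orders[, ep]
      starts <- seq(1L, n, by = bs)
      eploss <- 0
      for (s in starts) {
        b <- ord[s:min(s + bs - 1L, n)]
        nb <- length(b)
        yb <- y[b]
        ## rows of Pfull for this batch, position fastest within sample
        prow <- as.vector(outer(seq_len(g$npos), (b - 1L) * g$npos, `+`))
        P <- Pfull[prow, , drop = FALSE]            # (nb*npos) x kk
        convPre <- P %*% W$convW
        convPre <- convPre + rep(W$convB, each = nb * g$npos)
        mask <- convPre > 0
        conv <- convPre * mask
        dim(conv) <- c(g$npos, nb, nf)
        pooled <- conv[g$poolMembers[[1]], , , drop = FALSE]
        for (t in seq_along(g$poolMembers)[-1])
          pooled <- pooled + conv[g$poolMembers[[t]], , , drop = FALSE]
        ## (ppp, nb, nf) -> flatten (nb, ppp*nf) in public neuron order
        F <- matrix(aperm(pooled, c(2L, 1L, 3L)), nrow = nb)
        F <- F[, g$flattenPerm, drop = FALSE]
        Z1 <- F %*% W$W1
        Z1 <- Z1 + rep(W$b1, each = nb)
        H <- Z1; H[H < 0] <- 0
        Z2 <- H %*% W$W2
        Z2 <- Z2 + rep(W$b2, each = nb)
        mx <- pmax(Z2[, 1], Z2[, 2])
        e1 <- exp(Z2[, 1] - mx); e2 <- exp(Z2[, 2] - mx)
        Zs <- e1 + e2
        p <- cbind(e1, e2) / Zs
        eploss <- eploss - sum(log(pmax(p[cbind(seq_len(nb), yb + 1L)],
                                        1e-300)))
        ## backward
        Yb <- cbind(1 - yb, yb)
        dZ2 <- (p - Yb) / nb
        gW2 <- crossprod(H, dZ2); gb2 <- colSums(dZ2)
        dH <- tcrossprod(dZ2, W$W2)
        dZ1 <- dH * (Z1 > 0)
        gW1 <- crossprod(F, dZ1); gb1 <- colSums(dZ1)
        dF <- tcrossprod(dZ1, W$W1)
        dPooled <- dF[, g$invFlattenPerm, drop = FALSE]
        ## (nb, ppp, nf) -> (ppp+1, nb, nf) with a zero sink row, then
        ## gather per conv position through poolParent
        dPooled <- aperm(array(dPooled, c(nb, g$ppp, nf)), c(2L, 1L, 3L))
        sink <- array(0, c(g$ppp + 1L, nb, nf))
        sink[seq_len(g$ppp), , ] <- dPooled
        dConv <- sink[g$poolParent, , , drop = FALSE]
        dim(dConv) <- c(nb * g$npos, nf)
        dConv <- dConv * mask
        gConvW <- crossprod(P, dConv)
        gConvB <- colSums(dConv)
        ## momentum update
        V$convW <- mom * V$convW - lr * gConvW
        V$convB <- mom * V$convB - lr * gConvB
        V$W1 <- mom * V$W1 - lr * gW1
        V$b1 <- mom * V$b1 - lr * gb1
        V$W2 <- mom * V$W2 - lr * gW2
        V$b2 <- mom * V$b2 - lr * gb2
        W$convW <- W$convW + V$convW; W$convB <- W$convB + V$convB
        W$W1 <- W$W1 + V$W1; W$b1 <- W$b1 + V$b1
        W$W2 <- W$W2 + V$W2; W$b2 <- W$b2 + V$b2
      }
      history[ep] <- eploss / n
    }
  }
  new("Cpf1Classifier", spec = spec,
      convW = W$convW, convB = W$convB, W1 = W$W1, b1 = W$b1,
      W2 = W$W2, b2 = W$b2, threshold = clf@threshold, trained = TRUE,
      seed = clf@seed, history = history)
}

#' Predict positive-class scores
#'
#' Returns one score in `[0, 1]` per input (the softmax probability of the
#' positive class), in input order; scores do not depend on how the inputs
#' are batched.
#'
#' @param object a [Cpf1Classifier-class].
#' @param X list of [OneHotMatrix-class]/matrix inputs.
#' @param batchSize inference batch size (memory knob only).
#' @param ... ignored.
#' @return numeric vector of scores.
#' @export
setMethod("predict", "Cpf1Classifier", function(object, X, batchSize = 256L,
                                                ...) {
  Xmat <- stackInputs(X, object@spec)
  g <- netGeometry(object@spec)
  n <- nrow(Xmat)
  out <- numeric(n)
  for (s in seq(1L, n, by = batchSize)) {
    b <- s:min(s + batchSize - 1L, n)
    F <- forwardFlattenCore(Xmat[b, , drop = FALSE], object, g)$F
    out[b] <- forwardHead(F, object)$p
  }
  out
})

#' Receptive field of a flatten-layer neuron
#'
#' Flatten neurons are ordered map-major, then row-major within each pooled
#' map. Neuron n of map m corresponds to pooled cell (r, c); through the sum
#' pooling and valid convolution, its activation depends exactly on the
#' input rectangle rows `[ph*(r-1)+1, ph*(r-1)+kh+ph-1]`, columns
#' `[pw*(c-1)+1, pw*(c-1)+kw+pw-1]` (1-based, inclusive). The field is
#' purely structural: it depends on the [NetSpec-class], never on weights.
#'
#' @param neuron 1-based flatten neuron index.
#' @param spec a [NetSpec-class].
#' @return list with `map`, `pooledCell` (r, c), and integer vectors `rows`,
#'   `cols` delimiting the input rectangle.
#' @export
flattenReceptiveField <- function(neuron, spec) {
  fs <- flattenSize(spec)
  if (!isWholeNumber(neuron) || neuron < 1 || neuron > fs)
    stop(sprintf("neuron index must be in 1..%d", fs))
  ps <- pooledShape(spec)
  ppp <- prod(ps)
  map <- (neuron - 1L) %/% ppp + 1L
  within <- (neuron - 1L) %% ppp
  r <- within %/% ps[2] + 1L
  c <- within %% ps[2] + 1L
  ph <- spec@pool[1]; pw <- spec@pool[2]
  kh <- spec@kernel[1]; kw <- spec@kernel[2]
  rows <- (ph * (r - 1L) + 1L):(ph * (r - 1L) + kh + ph - 1L)
  cols <- (pw * (c - 1L) + 1L):(pw * (c - 1L) + kw + pw - 1L)
  list(map = map, pooledCell = c(r, c), rows = rows, cols = cols)
}

#' Serialize / restore a classifier
#'
#' Writes spec, weights, threshold and seed to a single versioned file;
#' reloading reproduces predictions bit-exactly. Loading a file with a
#' different format version fails.
#'
#' @param clf a [Cpf1Classifier-class].
#' @param path file path.
#' @return `writeClassifier`: invisibly, `path`; `readClassifier`: the
#'   restored [Cpf1Classifier-class].
#' @export
writeClassifier <- function(clf, path) {
  stopifnot(is(clf, "Cpf1Classifier"))
  s <- clf@spec
  obj <- list(
    format = "cpf1design-classifier", version = 1L,
    spec = list(inputShape = s@inputShape, nFilters = s@nFilters,
                kernel = s@kernel, pool = s@pool, denseUnits = s@denseUnits,
                learningRate = s@learningRate, momentum = s@momentum,
                batchSize = s@batchSize, epochs = s@epochs),
    convW = clf@convW, convB = clf@convB, W1 = clf@W1, b1 = clf@b1,
    W2 = clf@W2, b2 = clf@b2, threshold = clf@threshold,
    trained = clf@trained, seed = clf@seed, history = clf@history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cpf1design-classifier"))
    stop("not a cpf1design classifier file")
  if (!identical(obj$version, 1L))
    stop(sprintf("unsupported classifier file version %s", obj$version))
  spec <- do.call(netSpec, obj$spec[c("inputShape", "nFilters", "kernel",
                                      "pool", "denseUnits", "learningRate",
                                      "momentum", "batchSize", "epochs")])
  new("Cpf1Classifier", spec = spec,
      convW = obj$convW, convB = obj$convB, W1 = obj$W1, b1 = obj$b1,
      W2 = obj$W2, b2 = obj$b2, threshold = obj$threshold,
      trained = obj$trained, seed = obj$seed, history = obj$history)
}
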