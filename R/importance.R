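#' Permutation importance of flatten-layer neurons
#'
#' Quantifies how much each flatten neuron contributes to classification by
#' permuting its activation column across samples while all other neurons
#' keep their values, and measuring the mean decrease of a performance
#' criterion relative to the unpermuted baseline. Two criteria are offered:
#'
#' * `"auc"` (default): mean decrease in ROC AUC of the classifier's own
#'   dense head when the neuron is permuted. Because a permutation changes a
#'   single flatten column, the head is re-evaluated via a rank-one update
#'   of the dense pre-activations, which makes scoring all neurons cheap.
#' * `"impurity"`: mean decrease in node impurity (Gini) of a seeded
#'   random-forest surrogate fitted on the flatten activations; the forest's
#'   own permutation machinery is bypassed and its impurity decrease is
#'   reported per neuron.
#'
#' Negative decreases are possible and are reported as-is.
#'
#' @param clf a trained [Cpf1Classifier-class].
#' @param X list of encoded inputs.
#' @param y binary labels (0/1), both classes present.
#' @param nRepeats permutations per neuron (criterion `"auc"`).
#' @param seed integer seed.
#' @param criterion `"auc"` or `"impurity"`.
#' @param nTree forest size for the impurity surrogate.
#' @return object of class `importanceReport`: list with `neuronScores`
#'   (one per flatten neuron), `topIndices` (neurons ranked by decreasing
#'   score), `criterion` and `baseline` (baseline AUC, or NA for impurity).
#' @export
permutationImportance <- function(clf, X, y, nRepeats = 5L, seed = 1L,
                                  criterion = c("auc", "impurity"),
                                  nTree = 100L) {
  criterion <- match.arg(criterion)
  stopifnot(is(clf, "Cpf1Classifier"))
  if (!clf@trained) stop("classifier must be trained")
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  F <- flattenActivations(clf, X)
  stopifnot(nrow(F) == length(y))
  fs <- ncol(F)
  if (criterion == "impurity") {
    rf <- withSeed(seed, randomForest::randomForest(
      x = F, y = factor(y), ntree = nTree, importance = FALSE))
    scores <- as.numeric(rf$importance[, "MeanDecreaseGini"])
    baseline <- NA_real_
  } else {
    n <- nrow(F)
    Z1 <- F %*% clf@W1
    Z1 <- Z1 + rep(clf@b1, each = n)
    ## AUC is invariant to the monotone softmax, so rank on the class-score
    ## margin H %*% (W2[,2] - W2[,1]) instead of the full head; permuting
    ## one flatten column is a rank-one update of Z1 (compiled inner loop).
    wDiff <- clf@W2[, 2] - clf@W2[, 1]
    perms <- withSeed(seed, vapply(seq_len(nRepeats),
                                   function(r) sample.int(n), integer(n)))
    res <- .cppPermImportance(F, Z1, clf@W1, wDiff, y, perms)
    scores <- as.numeric(res$scores)
    baseline <- res$baseline
  }
  structure(list(neuronScores = scores,
                 topIndices = order(-scores, seq_len(fs)),
                 criterion = criterion, baseline = baseline),
            class = "importanceReport")
}

#' @export
print.importanceReport <- function(x, ...) {
  cat(sprintf(
    "Permutation importance (%s): %d neurons, top score %.4g%s\n",
    x$criterion, length(x$neuronScores), max(x$neuronScores),
    if (is.na(x$baseline)) "" else sprintf(" (baseline AUC %.3f)",
                                           x$baseline)))
  invisible(x)
}

#' Project top-ranked neurons onto the input matrix
#'
#' Sums the indicator masks of the receptive fields of the `topN`
#' highest-scoring flatten neurons, yielding a heatmap over input cells that
#' shows which sequence regions drive the classifier. The projection is
#' purely structural: it uses only the architecture, never the weights.
#'
#' @param importance an `importanceReport` from [permutationImportance()],
#'   or a numeric vector of neuron scores.
#' @param spec the classifier's [NetSpec-class].
#' @param topN number of top neurons to project (default 50).
#' @param rowLabels optional category labels for the heatmap rows (e.g.
#'   [kmerLabels()] or [mismatchLabels()]).
#' @return numeric matrix of the spec's input shape; entry (r, c) counts the
#'   selected neurons whose receptive field covers input cell (r, c).
#' @export
projectTopFeatures <- function(importance, spec, topN = 50L,
                               rowLabels = NULL) {
  scores <- if (inherits(importance, "importanceReport"))
    importance$neuronScores else importance
  fs <- flattenSize(spec)
  stopifnot(length(scores) == fs)
  if (topN < 1L || topN > fs)
    stop(sprintf("topN must be in 1..%d", fs))
  top <- order(-scores, seq_len(fs))[seq_len(topN)]
  heat <- matrix(0, spec@inputShape[1], spec@inputShape[2])
  for (i in top) {
    rf <- flattenReceptiveField(i, spec)
    heat[rf$rows, rf$cols] <- heat[rf$rows, rf$cols] + 1
  }
  dimnames(heat) <- list(rowLabels, seq_len(ncol(heat)))
  heat
}

#' Write a projection heatmap or ranked-neuron table as TSV
#'
#' @param heat matrix from [projectTopFeatures()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeHeatmap <- function(heat, path) {
  df <- data.frame(category = if (is.null(rownames(heat)))
    seq_len(nrow(heat)) else rownames(heat), heat, check.names = FALSE)
  colnames(df) <- c("category", paste0("pos", seq_len(ncol(heat))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
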