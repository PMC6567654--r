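#' Label records by efficacy cutoffs
#'
#' Sorts records by indel frequency in descending order (stable: ties keep
#' input order), labels the top `floor(topFrac * n)` records 1 ("most
#' effective") and the bottom `floor(bottomFrac * n)` records 0, and drops
#' the middle. With n = 1251 and 20%/20% this yields 250 + 250 = 500
#' labelled records.
#'
#' @param records data.frame with an `indel_frequency` column (e.g. from
#'   [simulateOnTarget()] or [readGuideDataset()]).
#' @param topFrac,bottomFrac fractions in (0, 1] with sum <= 1.
#' @return the labelled subset of `records` with a `label` column (1 = top,
#'   0 = bottom), top block first.
#' @export
labelByCutoffs <- function(records, topFrac = 0.2, bottomFrac = 0.2) {
  stopifnot(is.data.frame(records), "indel_frequency" %in% names(records),
            topFrac > 0, bottomFrac > 0, topFrac + bottomFrac <= 1)
  n <- nrow(records)
  nTop <- floor(topFrac * n)
  nBot <- floor(bottomFrac * n)
  if (nTop < 1L || nBot < 1L)
    stop("cutoffs select no records on one side")
  ord <- orderDesc(records$indel_frequency)
  sel <- c(ord[seq_len(nTop)], ord[(n - nBot + 1L):n])
  out <- records[sel, , drop = FALSE]
  out$label <- rep(c(1L, 0L), c(nTop, nBot))
  rownames(out) <- NULL
  out
}

#' Split records into labelled extremes and a held-out middle
#'
#' The training set is the labelled top/bottom extremes from
#' [labelByCutoffs()]; the test set is the excluded middle, kept with its
#' raw indel frequencies for correlation analysis. With n = 1251 and
#' 20%/20% cutoffs: train 500, test 751.
#'
#' @inheritParams labelByCutoffs
#' @return list with elements `train` (labelled) and `test` (middle).
#' @export
splitExtremes <- function(records, topFrac = 0.2, bottomFrac = 0.2) {
  train <- labelByCutoffs(records, topFrac, bottomFrac)
  n <- nrow(records)
  ord <- orderDesc(records$indel_frequency)
  nTop <- floor(topFrac * n); nBot <- floor(bottomFrac * n)
  mid <- ord[setdiff(seq_len(n), c(seq_len(nTop), (n - nBot + 1L):n))]
  test <- records[mid, , drop = FALSE]
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney rank statistic
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg); the returned
#' curve steps through score thresholds from high to low.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  ## collapse tied thresholds so the curve is a function of the cutoff
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[keep] / nNeg), tpr = c(0, tp[keep] / nPos))
  list(auc = auc, curve = curve)
}

#' F1 score at a threshold
#'
#' F1 = 2 TP / (2 TP + FP + FN), with scores at or above the threshold
#' called positive. Returns 0 when TP = 0.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @param threshold positive-call cutoff (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
f1AtThreshold <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  called <- scores >= threshold
  tp <- sum(called & labels == 1L)
  fp <- sum(called & labels == 0L)
  fn <- sum(!called & labels == 1L)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Spearman rank correlation
#'
#' Average-rank ties; returns NA with a warning when either vector is
#' constant (the correlation is undefined).
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or NA.
#' @export
spearmanRho <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (length(unique(predicted)) < 2L || length(unique(observed)) < 2L) {
    warning("Spearman correlation undefined for a constant vector")
    return(NA_real_)
  }
  cor(predicted, observed, method = "spearman")
}

#' Default trainer factory for external cross-validation
#'
#' Wraps [buildOnTargetNet()]/[buildOffTargetNet()] + [trainClassifier()]
#' into the trainer-callback signature used by [externalCV()] and
#' [cutoffGrid()]: `function(Xtrain, ytrain, seed)` returning a scorer
#' `function(Xnew) -> scores`.
#'
#' @param builder function(seed) returning an untrained
#'   [Cpf1Classifier-class].
#' @param epochs training epochs passed to [trainClassifier()].
#' @return a trainer callback.
#' @export
cnnTrainer <- function(builder, epochs = 100L) {
  force(builder); force(epochs)
  function(Xtrain, ytrain, seed) {
    clf <- trainClassifier(builder(seed), Xtrain, ytrain,
                           epochs = epochs, seed = seed)
    function(Xnew) predict(clf, Xnew)
  }
}

## Seeded stratified fold assignment: within each class, shuffled indices
## are dealt round-robin, so fold sizes differ by at most 1 and every fold
## keeps both classes whenever n per class >= k.
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      i <- which(y == cl)
      fold[i[sample.int(length(i))]] <- rep_len(sample.int(k), length(i))
    }
    fold
  })
}

#' External k-fold cross-validation
#'
#' Each fold is scored only by a model trained on the remaining k - 1 folds,
#' so every record is predicted exactly once by a model that never saw it.
#' Folds are a seeded stratified random partition (sizes differ by at most
#' one; both classes in every fold when feasible).
#'
#' @param X list of encoded inputs (or an n x D design matrix).
#' @param y binary labels (0/1).
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment and per-fold training.
#' @param trainer trainer callback, e.g. from [cnnTrainer()].
#' @return object of class `cvReport`: list with `foldAucs`, `meanAuc`,
#'   `sdAuc`, `foldSizes`, `fold` (per-record assignment) and `oofScores`
#'   (out-of-fold predictions, one per record).
#' @export
externalCV <- function(X, y, k = 5L, seed = 1L, trainer) {
  y <- as.integer(y)
  n <- if (is.matrix(X)) nrow(X) else length(X)
  stopifnot(length(y) == n, all(y %in% 0:1))
  if (n < k) stop("need at least k records for k-fold cross-validation")
  if (min(table(y)) < k)
    stop("too few records in one class to keep both classes in every fold")
  fold <- stratifiedFolds(y, k, seed)
  pick <- function(i) if (is.matrix(X)) X[i, , drop = FALSE] else X[i]
  oof <- numeric(n)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    scorer <- trainer(pick(tr), y[tr], seed + f)
    oof[te] <- scorer(pick(te))
    aucs[f] <- rocAuc(oof[te], y[te])$auc
  }
  structure(list(foldAucs = aucs, meanAuc = mean(aucs), sdAuc = sd(aucs),
                 foldSizes = tabulate(fold, k), fold = fold,
                 oofScores = oof),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("%d-fold external CV: AUC %.3f +/- %.3f (fold sizes %s)\n",
              length(x$foldAucs), x$meanAuc, x$sdAuc,
              paste(x$foldSizes, collapse = "/")))
  invisible(x)
}

#' Cross-validated AUC over a grid of efficacy cutoffs
#'
#' Re-labels the records for every (top, bottom) cutoff combination and runs
#' [externalCV()] on each labelling. The default 9 x 5 grid (top 5-45%,
#' bottom 60-80%, steps of 5) produces 45 combinations; combinations whose
#' fractions exceed 1 or select an empty class are reported as NA with a
#' reason rather than dropped.
#'
#' @param records data.frame with `sequence` and `indel_frequency`.
#' @param topFracs,bottomFracs numeric vectors of cutoff fractions.
#' @param trainer trainer callback (see [cnnTrainer()]).
#' @param k,seed cross-validation settings.
#' @param encoder function mapping a record data.frame to a list of encoded
#'   inputs; defaults to order-2 encoding of the `sequence` column.
#' @return data.frame with columns `topFrac`, `bottomFrac`, `meanAuc`,
#'   `sdAuc`, `note`.
#' @export
cutoffGrid <- function(records,
                       topFracs = seq(0.05, 0.45, by = 0.05),
                       bottomFracs = seq(0.60, 0.80, by = 0.05),
                       trainer, k = 5L, seed = 1L,
                       encoder = function(r) lapply(r$sequence, encodeOrderK,
                                                    k = 2)) {
  combos <- expand.grid(topFrac = topFracs, bottomFrac = bottomFracs,
                        KEEP.OUT.ATTRS = FALSE)
  out <- cbind(combos, meanAuc = NA_real_, sdAuc = NA_real_,
               note = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    tf <- combos$topFrac[i]; bf <- combos$bottomFrac[i]
    if (tf + bf > 1) {
      out$note[i] <- "infeasible: fractions sum beyond 1"
      next
    }
    lab <- tryCatch(labelByCutoffs(records, tf, bf), error = function(e) e)
    if (inherits(lab, "error")) {
      out$note[i] <- paste("infeasible:", conditionMessage(lab))
      next
    }
    cv <- externalCV(encoder(lab), lab$label, k = k, seed = seed,
                     trainer = trainer)
    out$meanAuc[i] <- cv$meanAuc
    out$sdAuc[i] <- cv$sdAuc
    out$note[i] <- "ok"
  }
  out
}
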