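test_that("efficacy cutoffs reproduce the 1251 -> 500/751 arithmetic", {
  set.seed(41)
  rec <- data.frame(sequence = replicate(1251, randomSeq(27)),
                    indel_frequency = runif(1251, 0, 100))
  lab <- labelByCutoffs(rec, 0.2, 0.2)
  expect_equal(nrow(lab), 500)
  expect_equal(sum(lab$label == 1), 250)
  expect_equal(sum(lab$label == 0), 250)
  sp <- splitExtremes(rec, 0.2, 0.2)
  expect_equal(nrow(sp$train), 500)
  expect_equal(nrow(sp$test), 751)
  ## train and test partition the input
  expect_setequal(c(sp$train$sequence, sp$test$sequence), rec$sequence)
  ## labels sit on the right side of the frequency ranking
  expect_true(min(lab$indel_frequency[lab$label == 1]) >=
              max(sp$test$indel_frequency))
  expect_true(max(lab$indel_frequency[lab$label == 0]) <=
              min(sp$test$indel_frequency))
})

test_that("cutoff labelling handles small n and degenerate requests", {
  rec <- data.frame(sequence = replicate(10, randomSeq(27)),
                    indel_frequency = 1:10)
  lab <- labelByCutoffs(rec, 0.5, 0.5)
  expect_equal(nrow(lab), 10)
  expect_equal(sum(lab$label), 5)
  sp5 <- splitExtremes(data.frame(sequence = replicate(5, randomSeq(27)),
                                  indel_frequency = 1:5), 0.2, 0.2)
  expect_equal(nrow(sp5$train), 2)
  expect_equal(nrow(sp5$test), 3)
  expect_error(labelByCutoffs(rec[1:3, ], 0.1, 0.1), "no records")
  ## stable tie handling: equal frequencies keep input order
  tie <- data.frame(sequence = replicate(4, randomSeq(27)),
                    indel_frequency = c(5, 5, 5, 5))
  lab2 <- labelByCutoffs(tie, 0.25, 0.25)
  expect_equal(lab2$sequence[lab2$label == 1], tie$sequence[1])
  expect_equal(lab2$sequence[lab2$label == 0], tie$sequence[4])
})

test_that("ROC AUC equals the exhaustive pairwise statistic", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4), c(1, 0, 1))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- sample(round(runif(n), 2))     # coarse grid forces ties
    expect_equal(rocAuc(scores, labels)$auc, pairwiseAuc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- 0:1
  a <- rocAuc(scores, labels)$auc
  expect_equal(rocAuc(exp(scores), labels)$auc, a)
  expect_equal(rocAuc(5 * scores - 3, labels)$auc, a)
  expect_equal(rocAuc(atan(scores), labels)$auc, a)
  ## curve endpoints and range
  r <- rocAuc(scores, labels)
  expect_true(all(r$curve$fpr >= 0 & r$curve$fpr <= 1))
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_gte(a, 0); expect_lte(a, 1)
})

test_that("F1 follows 2TP/(2TP+FP+FN)", {
  expect_equal(f1AtThreshold(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  ## TP=1, FP=1, FN=1 -> 0.5
  expect_equal(f1AtThreshold(c(0.9, 0.9, 0.1), c(1, 0, 1)), 0.5)
  ## TP=0 -> 0
  expect_equal(f1AtThreshold(c(0.1, 0.1), c(1, 0)), 0)
  ## threshold is inclusive
  expect_equal(f1AtThreshold(c(0.5, 0.4), c(1, 0), threshold = 0.5), 1)
})

test_that("Spearman correlation handles ranks and degenerate vectors", {
  expect_equal(spearmanRho(1:10, 1:10), 1.0)
  expect_equal(spearmanRho(1:10, 10:1), -1.0)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(out <- spearmanRho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})

test_that("external CV partitions records and recovers a planted rule", {
  d <- separableData(100, seed = 51)
  ## fast trainer scoring the planted dinucleotide directly exercises the
  ## CV machinery independently of the network
  ruleTrainer <- function(Xtr, ytr, seed) {
    function(Xnew) vapply(Xnew, function(s)
      as.numeric(substr(s, 12, 13) == "GG"), numeric(1))
  }
  cv <- externalCV(d$sequences, d$y, k = 5, seed = 1, trainer = ruleTrainer)
  expect_equal(cv$foldSizes, rep(20, 5))
  expect_equal(sort(unique(cv$fold)), 1:5)
  ## every record predicted exactly once, by construction of oofScores
  expect_equal(length(cv$oofScores), 100)
  expect_gte(cv$meanAuc, 0.95)
  ## folds are stratified: both classes everywhere
  for (f in 1:5) expect_equal(sort(unique(d$y[cv$fold == f])), 0:1)
  expect_error(externalCV(d$sequences[1:4], d$y[1:4], k = 5,
                          trainer = ruleTrainer), "at least k")
})

test_that("the cutoff grid covers 45 combinations and flags infeasible ones", {
  set.seed(52)
  rec <- data.frame(sequence = replicate(120, randomSeq(27)),
                    indel_frequency = runif(120, 0, 100))
  gcTrainer <- function(Xtr, ytr, seed) {
    function(Xnew) vapply(Xnew, function(s) {
      ch <- strsplit(s, "")[[1]]
      mean(ch %in% c("G", "C"))
    }, numeric(1))
  }
  grid <- cutoffGrid(rec, trainer = gcTrainer, seed = 1,
                     encoder = function(r) r$sequence)
  expect_equal(nrow(grid), 45)
  infeasible <- grid$topFrac + grid$bottomFrac > 1
  expect_true(all(is.na(grid$meanAuc[infeasible])))
  expect_true(all(grepl("infeasible", grid$note[infeasible])))
  expect_true(all(!is.na(grid$meanAuc[!infeasible])))
  ## a 1x1 grid reduces to externalCV on that labelling
  g1 <- cutoffGrid(rec, topFracs = 0.3, bottomFracs = 0.3,
                   trainer = gcTrainer, seed = 7,
                   encoder = function(r) r$sequence)
  lab <- labelByCutoffs(rec, 0.3, 0.3)
  cv <- externalCV(lab$sequence, lab$label, k = 5, seed = 7,
                   trainer = gcTrainer)
  expect_equal(g1$meanAuc[1], cv$meanAuc)
})
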