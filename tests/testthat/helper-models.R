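## Shared fixtures, built once per test session.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(L) paste(sample(BASES, L, replace = TRUE),
                               collapse = "")

randomTarget <- function() paste0("TTT", randomSeq(24))

## Substitute one base at each of `pos`, returning the mutated string.
mutateAt <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

## Sequences whose class is decided by one dinucleotide: positives carry
## "GG" at protospacer positions 12-13, negatives never do.
separableData <- function(n, seed = 42) {
  withr::local_seed(seed)
  y <- rep(0:1, length.out = n)
  seqs <- vapply(y, function(lab) {
    ch <- sample(BASES, 27, replace = TRUE)
    if (lab == 1) {
      ch[12] <- "G"; ch[13] <- "G"
    } else if (ch[12] == "G" && ch[13] == "G") ch[13] <- "A"
    paste(ch, collapse = "")
  }, character(1))
  list(sequences = seqs, y = y)
}

## Trained models shared across test files (training is the expensive step,
## so build lazily and cache).
.modelCache <- new.env(parent = emptyenv())

sharedOnTargetModel <- function() {
  if (is.null(.modelCache$on)) {
    rec <- simulateOnTarget(1500, seed = 7001)
    lab <- labelByCutoffs(rec, 0.2, 0.2)
    X <- lapply(lab$sequence, encodeOrderK, k = 2)
    .modelCache$on <- trainClassifier(buildOnTargetNet(11), X, lab$label,
                                      epochs = 12, seed = 11)
  }
  .modelCache$on
}

sharedOffTargetModel <- function() {
  if (is.null(.modelCache$off)) {
    mm <- simulateMismatch(2000, seed = 7002)
    lab <- labelByCutoffs(mm, 0.2, 0.8)
    X <- mapply(encodeMismatchPair, lab$guide, lab$target, SIMPLIFY = FALSE)
    .modelCache$off <- trainClassifier(buildOffTargetNet(12), X, lab$label,
                                       epochs = 15, seed = 12)
  }
  .modelCache$off
}

## Brute-force ROC AUC: count of concordant pairs plus half-ties.
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Naive quadratic off-target scan: slide over every offset on both
## strands, check the TTTN PAM and count protospacer mismatches directly.
naiveOffTargetScan <- function(guideSeq, s, maxMismatch,
                               excludeStart = NULL, excludeStrand = NULL) {
  gp <- strsplit(substr(guideSeq, 5, 27), "", fixed = TRUE)[[1]]
  L <- nchar(s)
  hits <- data.frame(start = integer(), strand = character(),
                     mismatchCount = integer())
  for (i in seq_len(L - 26L)) {
    for (std in c("+", "-")) {
      site <- if (std == "+") substr(s, i, i + 26L)
              else reverseComplementStr(substr(s, i, i + 26L))
      if (substr(site, 1, 3) != "TTT" || grepl("N", site, fixed = TRUE))
        next
      sp <- strsplit(substr(site, 5, 27), "", fixed = TRUE)[[1]]
      mmc <- sum(sp != gp)
      if (mmc > maxMismatch) next
      if (!is.null(excludeStart) && i == excludeStart &&
          std == excludeStrand) next
      hits <- rbind(hits, data.frame(start = i, strand = std,
                                     mismatchCount = mmc))
    }
  }
  hits
}
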