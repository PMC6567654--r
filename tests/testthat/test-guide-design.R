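test_that("candidate discovery finds TTTN-N23 sites on both strands", {
  g <- paste0("TTTA", strrep("ACG", 7), "AC")     # TTT-free protospacer
  plus <- findCandidateSites(c(s1 = g))
  expect_length(plus, 1)
  expect_equal(GenomicRanges::start(plus), 1)
  expect_equal(GenomicRanges::end(plus), 27)
  expect_equal(as.character(GenomicRanges::strand(plus)), "+")
  minus <- findCandidateSites(c(s1 = reverseComplementStr(g)))
  expect_length(minus, 1)
  expect_equal(as.character(GenomicRanges::strand(minus)), "-")
  expect_equal(minus$sequence, g)                 # PAM-first orientation
  ## no TTT on either strand -> no sites
  expect_length(findCandidateSites(c(s1 = strrep("ACG", 34))), 0)
  ## N-containing windows are skipped
  withN <- sub("^TTTA.", "TTTAN", g)
  expect_length(findCandidateSites(c(s1 = withN)), 0)
})

test_that("every candidate re-validates against its genomic slice", {
  set.seed(71)
  s <- randomSeq(5000)
  sites <- findCandidateSites(c(chrX = s))
  expect_gt(length(sites), 0)
  expect_true(all(GenomicRanges::width(sites) == 27))
  expect_true(all(substr(sites$sequence, 1, 3) == "TTT"))
  slice <- substring(s, GenomicRanges::start(sites),
                     GenomicRanges::end(sites))
  onMinus <- as.character(GenomicRanges::strand(sites)) == "-"
  expect_identical(sites$sequence[!onMinus], slice[!onMinus])
  expect_identical(sites$sequence[onMinus],
                   reverseComplementStr(slice[onMinus]))
  ## strand symmetry: a sequence and its reverse complement carry the same
  ## number of candidates
  expect_equal(length(sites),
               length(findCandidateSites(c(chrX = reverseComplementStr(s)))))
})

test_that("GC and polyT filters apply strict bounds and are idempotent", {
  gc0 <- paste0("TTTA", strrep("A", 23))          # GC = 0
  gc7 <- paste0("TTTA", strrep("G", 7), strrep("A", 16))  # 7/23 = 0.304
  gcHi <- paste0("TTTA", strrep("G", 23))         # GC = 1
  polyt <- paste0("TTTA", "ACGTTTTA", strrep("ACG", 5))   # TTTT run
  sites <- findCandidateSites(c(a = gc0, b = gc7, c = gcHi, d = polyt))
  plusOnly <- sites[as.character(GenomicRanges::strand(sites)) == "+"]
  kept <- applyFilters(plusOnly)
  keptSeq <- kept$sequence
  expect_true(gc7 %in% keptSeq)
  expect_false(gc0 %in% keptSeq)
  expect_false(gcHi %in% keptSeq)
  expect_false(polyt %in% keptSeq)
  rem <- attr(kept, "removed")
  expect_setequal(rem$reason, c("gc_below_min", "gc_above_max", "polyT"))
  ## idempotent
  again <- applyFilters(kept)
  expect_equal(length(again), length(kept))
  expect_equal(nrow(attr(again, "removed")), 0)
})

test_that("activity ranking retains the top fraction with a floor of one", {
  set.seed(72)
  clf <- sharedOnTargetModel()
  s <- randomSeq(30000)
  sites <- applyFilters(findCandidateSites(c(g1 = s)))
  stopifnot(length(sites) >= 20)
  hundred <- sites[seq_len(min(100, length(sites)))]
  kept <- rankAndRetain(hundred, clf, retainFrac = 0.10)
  expect_equal(length(kept), 10)
  expect_false(is.unsorted(rev(kept$activity)))
  one <- rankAndRetain(sites[1], clf, retainFrac = 0.10)
  expect_length(one, 1)
  ## ranking is invariant to input order
  shuf <- rankAndRetain(hundred[sample(100)], clf, retainFrac = 0.10)
  expect_identical(GenomicRanges::start(kept), GenomicRanges::start(shuf))
  expect_identical(kept$sequence, shuf$sequence)
})

test_that("off-target enumeration agrees exactly with a naive re-scan", {
  set.seed(73)
  guide <- paste0("TTTG", randomSeq(23))
  sim <- simulateGenome(12000, planted = list(
    list(guide = guide, nCopies = 2, nMismatches = 2),
    list(guide = guide, nCopies = 1, nMismatches = 4)), seed = 81)
  for (mmax in c(0L, 2L, 4L)) {
    hits <- enumerateOffTargets(guide, sim$sequence, maxMismatch = mmax)
    ref <- naiveOffTargetScan(guide, sim$sequence[[1]], mmax)
    hd <- data.frame(start = GenomicRanges::start(hits),
                     strand = as.character(GenomicRanges::strand(hits)),
                     mismatchCount = hits$mismatchCount)
    ord <- function(d) d[order(d$start, d$strand), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(hd))), unname(as.matrix(ord(ref))))
  }
  ## planted-truth counts: 2 two-mismatch + 1 four-mismatch copies
  expect_equal(length(enumerateOffTargets(guide, sim$sequence, 1)), 0)
  expect_equal(length(enumerateOffTargets(guide, sim$sequence, 2)), 2)
  expect_equal(length(enumerateOffTargets(guide, sim$sequence, 4)), 3)
  ## hit count is invariant to reverse-complementing the whole genome
  rcGenome <- c(synth1 = reverseComplementStr(sim$sequence[[1]]))
  expect_equal(length(enumerateOffTargets(guide, rcGenome, 4)), 3)
  ## the guide's own locus is excluded when coordinates are known
  sim2 <- simulateGenome(5000, planted = list(
    list(guide = guide, nCopies = 1, nMismatches = 0)), seed = 82)
  own <- findCandidateSites(sim2$sequence)
  own <- own[own$sequence == guide]
  expect_length(own, 1)
  hitsOwn <- enumerateOffTargets(own, sim2$sequence, maxMismatch = 0)
  expect_length(hitsOwn, 0)
})

test_that("specificity scoring counts predicted high-activity hits", {
  clfOff <- sharedOffTargetModel()
  guide <- paste0("TTTG", strrep("ACG", 7), "CA")
  empty <- enumerateOffTargets(guide, c(x = strrep("ACG", 400)), 3)
  sc0 <- specificityScore(guide, empty, clfOff)
  expect_equal(sc0$nHigh, 0L)
  expect_equal(sc0$specificity, 1)
  ## region penalty recovered: promiscuous-region mismatches score higher
  ## than the same number of seed-region mismatches
  set.seed(74)
  promScores <- replicate(20, {
    g <- randomTarget()
    predict(clfOff, list(encodeMismatchPair(g, mutateAt(g, sample(23:27, 2)))))
  })
  seedScores <- replicate(20, {
    g <- randomTarget()
    predict(clfOff, list(encodeMismatchPair(g, mutateAt(g, sample(5:10, 2)))))
  })
  expect_gt(mean(promScores), mean(seedScores))
  ## specificity is monotone decreasing in the number of high hits
  expect_gt(1 / (1 + 0), 1 / (1 + 1))
})

test_that("library design ranks clean guides above off-target-burdened ones", {
  set.seed(75)
  clfOn <- sharedOnTargetModel()
  clfOff <- sharedOffTargetModel()
  ## plant a high-activity guide (T-free seed region) twice: each copy sees
  ## the other as a perfect off-target
  dup <- paste0("TTTG", "ACGACG", randomSeq(17))
  sim <- simulateGenome(20000,
                        planted = list(list(guide = dup, nCopies = 2,
                                            nMismatches = 0)),
                        seed = 91)
  des <- designLibrary(sim$sequence, clfOn, clfOff, nGuides = 10,
                       retainFrac = 0.25, maxMismatch = 3)
  g <- des@guides
  expect_lte(length(g), 10)
  ## final order is lexicographic: nHigh ascending, then activity descending
  expect_false(is.unsorted(g$nHighOffTargets))
  for (lvl in unique(g$nHighOffTargets)) {
    sub <- g[g$nHighOffTargets == lvl]
    expect_false(is.unsorted(rev(sub$activity)))
  }
  ## the planted duplicates are seen and burdened
  dupRows <- which(g$sequence == dup)
  if (length(dupRows)) {
    expect_true(all(g$nHighOffTargets[dupRows] >= 1))
    cleanAfter <- which(g$nHighOffTargets == 0)
    if (length(cleanAfter))
      expect_true(all(max(cleanAfter) < min(dupRows)))
  }
  ## determinism: same inputs, same design
  des2 <- designLibrary(sim$sequence, clfOn, clfOff, nGuides = 10,
                        retainFrac = 0.25, maxMismatch = 3)
  expect_identical(GenomicRanges::start(des@guides),
                   GenomicRanges::start(des2@guides))
  ## shortfall flag when asking for more guides than survive
  expect_warning(
    small <- designLibrary(c(s = paste0(strrep("ACG", 20), dup,
                                        strrep("CGA", 20))),
                           clfOn, clfOff, nGuides = 10),
    "survived")
  expect_true(small@shortfall)
})

test_that("design exports are well-formed BED6 and TSV", {
  clfOn <- sharedOnTargetModel()
  clfOff <- sharedOffTargetModel()
  set.seed(76)
  sim <- simulateGenome(15000, seed = 92)
  des <- designLibrary(sim$sequence, clfOn, clfOff, nGuides = 5,
                       retainFrac = 0.2, maxMismatch = 2)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ots <- withr::local_tempfile(fileext = ".tsv")
  writeGuidesBed(des, bed)
  writeGuidesTsv(des, tsv)
  writeOffTargetsTsv(des, ots)
  b <- read.delim(bed, header = FALSE)
  expect_equal(ncol(b), 6)
  expect_equal(b$V3 - b$V2, rep(27, nrow(b)))     # half-open 27-nt span
  expect_true(all(b$V5 >= 0 & b$V5 <= 1000))
  expect_true(all(b$V6 %in% c("+", "-")))
  t <- read.delim(tsv)
  expect_equal(nrow(t), length(des@guides))
  expect_true(all(c("sequence", "activity", "nHighOffTargets",
                    "specificity") %in% names(t)))
})
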