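#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importFrom GenomicRanges GRanges GRangesList mcols mcols<- strand start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## Coerce character / DNAString / DNAStringSet input to a named uppercase
## character vector of sequences.
asSequences <- function(sequences, name = "seq1") {
  if (is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is(sequences, "DNAString")) {
    out <- stats::setNames(as.character(sequences), name)
  } else {
    stopifnot(is.character(sequences))
    out <- toupper(sequences)
    if (is.null(names(out)))
      names(out) <- if (length(out) == 1L) name
                    else paste0(name, seq_along(out))
  }
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop(sprintf("sequence '%s' contains characters outside {A,C,G,T,N}",
                 names(out)[bad][1]))
  out
}

## One-strand TTTN-N23 scan of a plain character sequence; returns 1-based
## start positions of N-free 27-nt sites.
scanTTTN <- function(s) {
  L <- nchar(s)
  if (L < 27L) return(integer(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  isT <- chars == "T"
  starts <- which(isT[seq_len(L - 26L)] &
                  isT[2:(L - 25L)] &
                  isT[3:(L - 24L)])
  if (!length(starts)) return(integer(0))
  nN <- cumsum(chars == "N")
  hasN <- (nN[starts + 26L] - c(0L, nN)[starts]) > 0L
  starts[!hasN]
}

protospacerOf <- function(seq27) substr(seq27, 5L, 27L)

gcFractionOf <- function(proto) {
  vapply(strsplit(proto, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

hasPolyTRun <- function(proto, runLength = 4L) {
  grepl(strrep("T", runLength), proto, fixed = TRUE)
}

#' Find candidate Cpf1 target sites (TTTN-N23 scan)
#'
#' Scans both strands of each input sequence for a TTTN PAM followed by a
#' 23-nt protospacer. Overlapping sites are all reported; windows containing
#' N are skipped. Coordinates are 1-based forward-strand ranges of width 27
#' (GRanges convention); the `sequence` metadata column is always PAM-first,
#' i.e. the reverse complement of the genomic slice for minus-strand sites.
#'
#' @param sequences named character vector, `DNAString` or `DNAStringSet`.
#' @param name sequence name used when `sequences` is unnamed.
#' @param polytRun run length used for the `hasPolyT` annotation.
#' @return [GenomicRanges::GRanges] with metadata columns `sequence`,
#'   `protospacer`, `gcFraction`, `hasPolyT`.
#' @export
findCandidateSites <- function(sequences, name = "seq1", polytRun = 4L) {
  seqs <- asSequences(sequences, name)
  subseq27 <- function(x, at) {
    if (length(at) == 0L) character(0) else substring(x, at, at + 26L)
  }
  parts <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    L <- nchar(s)
    plus <- scanTTTN(s)
    rc <- reverseComplementStr(s)
    minusRc <- scanTTTN(rc)           # starts on the reverse complement
    minus <- L - minusRc - 25L        # forward-strand 1-based starts
    data.frame(
      seqnames = rep(nm, length(plus) + length(minusRc)),
      start = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minusRc))),
      sequence = c(subseq27(s, plus), subseq27(rc, minusRc)))
  })
  df <- do.call(rbind, parts)
  gr <- GRanges(factor(df$seqnames, levels = names(seqs)),
                IRanges(start = df$start, width = 27L),
                strand = df$strand)
  mcols(gr)$sequence <- df$sequence
  gr <- gr[order(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)))]
  proto <- protospacerOf(mcols(gr)$sequence)
  mcols(gr)$protospacer <- proto
  mcols(gr)$gcFraction <- gcFractionOf(proto)
  mcols(gr)$hasPolyT <- hasPolyTRun(proto, polytRun)
  gr
}

#' Filter candidate sites on GC content and polyT runs
#'
#' Removes sites whose 23-nt protospacer GC fraction is strictly below
#' `gcMin` or strictly above `gcMax`, or which contain a run of at least
#' `polytRun` consecutive T within the protospacer (a polyT stretch
#' terminates Pol III transcription of the crRNA). Removal reasons are
#' attached as attribute `"removed"` (a data.frame). Idempotent.
#'
#' @param sites GRanges from [findCandidateSites()].
#' @param gcMin,gcMax GC bounds, default 0.30 / 0.70 (strict inequalities).
#' @param polytRun minimum T-run length that disqualifies a site.
#' @return the retained GRanges.
#' @export
applyFilters <- function(sites, gcMin = 0.30, gcMax = 0.70, polytRun = 4L) {
  stopifnot(is(sites, "GRanges"))
  gc <- mcols(sites)$gcFraction
  polyt <- hasPolyTRun(mcols(sites)$protospacer, polytRun)
  reason <- ifelse(gc < gcMin, "gc_below_min",
            ifelse(gc > gcMax, "gc_above_max",
            ifelse(polyt, "polyT", NA_character_)))
  keep <- is.na(reason)
  out <- sites[keep]
  attr(out, "removed") <- data.frame(
    seqnames = as.character(seqnames(sites))[!keep],
    start = start(sites)[!keep],
    strand = as.character(strand(sites))[!keep],
    reason = reason[!keep])
  out
}

#' Score candidates and retain the most active fraction
#'
#' Scores each site's 27-nt sequence with the on-target classifier
#' (order-2 encoding) and keeps the top `ceiling(retainFrac * n)` sites
#' (never fewer than one). Ties and the final order are broken by
#' coordinate, so the result is invariant to input order.
#'
#' @param sites filtered GRanges.
#' @param clfOn trained on-target [Cpf1Classifier-class] (16 x 26 inputs).
#' @param retainFrac fraction retained (default 0.10).
#' @return GRanges of retained sites with an `activity` metadata column,
#'   sorted by decreasing activity.
#' @export
rankAndRetain <- function(sites, clfOn, retainFrac = 0.10) {
  stopifnot(is(sites, "GRanges"))
  if (length(sites) == 0L) stop("no candidate sites to rank")
  ## canonical coordinate order first, so score ties break by coordinate
  sites <- sites[order(as.character(seqnames(sites)), start(sites),
                       as.character(strand(sites)))]
  X <- lapply(mcols(sites)$sequence, encodeOrderK, k = 2)
  mcols(sites)$activity <- predict(clfOn, X)
  nKeep <- max(1L, ceiling(retainFrac * length(sites)))
  ord <- order(-mcols(sites)$activity, seq_along(sites))
  sites[ord[seq_len(nKeep)]]
}

#' Enumerate off-target sites of a guide
#'
#' Exhaustively scans both strands of the given sequences for TTTN-PAM sites
#' whose 23-nt protospacer differs from the guide's protospacer by at most
#' `maxMismatch` substitutions (the PAM must match TTTN exactly; position 4
#' is free). The guide's own locus, when its coordinates are supplied, is
#' excluded.
#'
#' @param guide a length-1 GRanges with a `sequence` metadata column (e.g.
#'   one element of [rankAndRetain()] output), or a plain 27-nt string.
#' @param sequences named character vector / `DNAStringSet` to scan.
#' @param maxMismatch maximum protospacer mismatches (<= 7).
#' @param sites optional precomputed [findCandidateSites()] result for
#'   `sequences`, so repeated queries against the same sequences skip the
#'   scan.
#' @return GRanges of hits with metadata columns `sequence`, `protospacer`,
#'   `mismatchCount` and `mismatchPositions` (comma-separated positions in
#'   1..27 coordinates of the PAM-first site).
#' @export
enumerateOffTargets <- function(guide, sequences, maxMismatch = 4L,
                                sites = NULL) {
  stopifnot(isWholeNumber(maxMismatch), maxMismatch >= 0, maxMismatch <= 7)
  if (is(guide, "GRanges")) {
    stopifnot(length(guide) == 1L)
    guideSeq <- mcols(guide)$sequence
    own <- guide
  } else {
    stopifnot(is.character(guide), nchar(guide) == 27L)
    guideSeq <- toupper(guide)
    own <- NULL
  }
  if (is.null(sites)) sites <- findCandidateSites(sequences)
  gp <- strsplit(protospacerOf(guideSeq), "", fixed = TRUE)[[1]]
  proto <- mcols(sites)$protospacer
  mm <- integer(length(sites))
  for (p in seq_len(23L))
    mm <- mm + (substr(proto, p, p) != gp[p])
  keep <- mm <= maxMismatch
  if (!is.null(own)) {
    self <- as.character(seqnames(sites)) == as.character(seqnames(own)) &
      start(sites) == start(own) &
      as.character(strand(sites)) == as.character(strand(own))
    keep <- keep & !self
  }
  hits <- sites[keep]
  mcols(hits)$mismatchCount <- mm[keep]
  gfull <- strsplit(guideSeq, "", fixed = TRUE)[[1]]
  mcols(hits)$mismatchPositions <- vapply(
    strsplit(mcols(hits)$sequence, "", fixed = TRUE),
    function(ch) paste(which(ch != gfull), collapse = ","), character(1))
  mcols(hits)$gcFraction <- NULL
  mcols(hits)$hasPolyT <- NULL
  hits
}

#' Specificity score of a guide from its predicted off-target activity
#'
#' Encodes every hit as a guide/site mismatch matrix, scores it with the
#' off-target classifier, counts hits at or above the threshold
#' ("predicted high-activity off-target sites"), and converts the count to
#' a normalized specificity score 1 / (1 + nHigh), which is 1 for a guide
#' with no predicted high-activity off-targets and decreases monotonically.
#'
#' @param guide length-1 GRanges with `sequence`, or a 27-nt string.
#' @param hits GRanges from [enumerateOffTargets()].
#' @param clfOff trained off-target [Cpf1Classifier-class] (12 x 27 inputs).
#' @param threshold high-activity call cutoff (default 0.5).
#' @return list with `nHigh`, `specificity`, and `hitScores` (one predicted
#'   score per hit, in hit order).
#' @export
specificityScore <- function(guide, hits, clfOff, threshold = 0.5) {
  stopifnot(is(clfOff, "Cpf1Classifier"))
  if (!clfOff@trained) stop("off-target classifier must be trained")
  guideSeq <- if (is(guide, "GRanges")) mcols(guide)$sequence
              else toupper(guide)
  if (length(hits) == 0L)
    return(list(nHigh = 0L, specificity = 1, hitScores = numeric(0)))
  X <- lapply(mcols(hits)$sequence, function(s)
    encodeMismatchPair(guideSeq, s))
  scores <- predict(clfOff, X)
  nHigh <- sum(scores >= threshold)
  list(nHigh = nHigh, specificity = 1 / (1 + nHigh), hitScores = scores)
}

#' Design an optimized guide RNA library
#'
#' End-to-end pipeline: TTTN-N23 candidate scan, GC/polyT filtering,
#' activity scoring with retention of the top fraction, off-target
#' enumeration and specificity scoring of the retained sites, and final
#' lexicographic ranking on (fewest predicted high-activity off-target
#' sites, highest activity, leftmost coordinate). Deterministic given the
#' trained models and parameters.
#'
#' @param sequences sequences to design against (named character vector or
#'   `DNAStringSet`); off-targets are enumerated over these same sequences.
#' @param clfOn,clfOff trained on-/off-target classifiers.
#' @param nGuides number of guides requested (default 10). When fewer
#'   candidates survive, all survivors are returned and the design's
#'   `shortfall` flag is set (with a warning).
#' @param gcMin,gcMax,polytRun filter parameters (see [applyFilters()]).
#' @param retainFrac activity retention fraction (see [rankAndRetain()]).
#' @param maxMismatch off-target mismatch limit (see
#'   [enumerateOffTargets()]).
#' @param threshold high-activity off-target cutoff.
#' @return a [LibraryDesign-class].
#' @export
designLibrary <- function(sequences, clfOn, clfOff, nGuides = 10L,
                          gcMin = 0.30, gcMax = 0.70, polytRun = 4L,
                          retainFrac = 0.10, maxMismatch = 4L,
                          threshold = 0.5) {
  seqs <- asSequences(sequences)
  sites <- findCandidateSites(seqs, polytRun = polytRun)
  kept <- applyFilters(sites, gcMin, gcMax, polytRun)
  if (length(kept) == 0L) stop("no candidate sites survive the filters")
  retained <- rankAndRetain(kept, clfOn, retainFrac)
  ots <- vector("list", length(retained))
  nHigh <- integer(length(retained))
  specs <- numeric(length(retained))
  for (i in seq_along(retained)) {
    hits <- enumerateOffTargets(retained[i], seqs, maxMismatch,
                                sites = sites)
    sc <- specificityScore(retained[i], hits, clfOff, threshold)
    if (length(hits)) mcols(hits)$predictedScore <- sc$hitScores
    ots[[i]] <- hits
    nHigh[i] <- sc$nHigh
    specs[i] <- sc$specificity
  }
  mcols(retained)$nHighOffTargets <- nHigh
  mcols(retained)$specificity <- specs
  ord <- order(nHigh, -mcols(retained)$activity,
               as.character(seqnames(retained)), start(retained))
  retained <- retained[ord]
  ots <- ots[ord]
  shortfall <- length(retained) < nGuides
  if (shortfall)
    warning(sprintf("only %d candidate(s) survived; %d requested",
                    length(retained), nGuides))
  take <- seq_len(min(nGuides, length(retained)))
  guides <- retained[take]
  names(guides) <- paste0("guide_", seq_along(guides))
  new("LibraryDesign",
      guides = guides,
      offTargets = GRangesList(stats::setNames(ots[take], names(guides))),
      params = list(nGuides = nGuides, gcMin = gcMin, gcMax = gcMax,
                    polytRun = polytRun, retainFrac = retainFrac,
                    maxMismatch = maxMismatch, threshold = threshold),
      shortfall = shortfall)
}

#' Export a library design
#'
#' `writeGuidesBed` writes BED6 (0-based half-open, name = guide id,
#' score = round(1000 * activity)); `writeGuidesTsv` writes the detailed
#' per-guide table; `writeOffTargetsTsv` writes all enumerated hits.
#'
#' @param design a [LibraryDesign-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGuidesBed <- function(design, path) {
  g <- design@guides
  bed <- data.frame(chrom = as.character(seqnames(g)),
                    start = start(g) - 1L,
                    end = end(g),
                    name = names(g),
                    score = round(1000 * mcols(g)$activity),
                    strand = as.character(strand(g)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGuidesBed
#' @export
writeGuidesTsv <- function(design, path) {
  g <- design@guides
  df <- data.frame(guide = names(g),
                   seqnames = as.character(seqnames(g)),
                   start = start(g), end = end(g),
                   strand = as.character(strand(g)),
                   sequence = mcols(g)$sequence,
                   gcFraction = mcols(g)$gcFraction,
                   hasPolyT = mcols(g)$hasPolyT,
                   activity = mcols(g)$activity,
                   nHighOffTargets = mcols(g)$nHighOffTargets,
                   specificity = mcols(g)$specificity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGuidesBed
#' @export
writeOffTargetsTsv <- function(design, path) {
  rows <- lapply(names(design@offTargets), function(nm) {
    h <- design@offTargets[[nm]]
    if (length(h) == 0L) return(NULL)
    data.frame(guide = nm,
               seqnames = as.character(seqnames(h)),
               start = start(h), end = end(h),
               strand = as.character(strand(h)),
               sequence = mcols(h)$sequence,
               mismatchCount = mcols(h)$mismatchCount,
               mismatchPositions = mcols(h)$mismatchPositions,
               predictedScore = mcols(h)$predictedScore)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(guide = character(), seqnames = character(),
               start = integer(), end = integer(), strand = character(),
               sequence = character(), mismatchCount = integer(),
               mismatchPositions = character(),
               predictedScore = numeric()))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
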