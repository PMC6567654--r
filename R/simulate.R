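## Protospacer region boundaries (positions of the 27-nt site, PAM = 1-4):
## mismatches in the seed region abolish cleavage most strongly, trunk
## mismatches have an intermediate effect, promiscuous-region mismatches a
## mild one.
SEED_POSITIONS <- 5:10
TRUNK_POSITIONS <- 11:22
PROMISCUOUS_POSITIONS <- 23:27

randomTarget27 <- function(n) {
  pam4 <- sample(DNA_BASES, n, replace = TRUE)
  proto <- vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, 23, replace = TRUE), collapse = ""), character(1))
  paste0("TTT", pam4, proto)
}

#' Simulate matched on-target records with a planted sequence effect
#'
#' Generates random TTTN + 23-nt target sequences whose latent activity
#' follows a logistic model penalizing thymines in the PAM-proximal seed
#' (positions 5-10) and rewarding balanced GC:
#' `activity = plogis(b0 - bT * nT(5:10) + bGC * (GC - 0.5))`, with
#' `indel_frequency = 100 * activity + N(0, sigma)` clipped to `[0, 100]`.
#' The planted effect gives every downstream module a known ground truth:
#' T-rich seeds are strictly less active, and the relevant input columns
#' are known for importance analysis.
#'
#' @param n number of records (>= 10).
#' @param seed integer seed.
#' @param b0,bT,bGC,sigma generator coefficients; defaults 0, 0.8, 1.0, 5.
#' @return data.frame with columns `sequence`, `indel_frequency`.
#' @export
simulateOnTarget <- function(n, seed = 1L, b0 = 0, bT = 0.8, bGC = 1.0,
                             sigma = 5) {
  stopifnot(isWholeNumber(n), n >= 10, sigma >= 0)
  withSeed(seed, {
    seqs <- randomTarget27(n)
    chars <- strsplit(seqs, "", fixed = TRUE)
    nT <- vapply(chars, function(ch) sum(ch[SEED_POSITIONS] == "T"),
                 numeric(1))
    gc <- vapply(chars, function(ch) mean(ch[5:27] %in% c("G", "C")),
                 numeric(1))
    act <- stats::plogis(b0 - bT * nT + bGC * (gc - 0.5))
    freq <- pmin(100, pmax(0, 100 * act + rnorm(n, 0, sigma)))
    data.frame(sequence = seqs, indel_frequency = freq)
  })
}

#' Simulate guide/target mismatch records with planted region penalties
#'
#' Each record pairs a random 27-nt guide with a copy carrying 1 to
#' `maxMismatches` substitutions at random protospacer positions (5-27).
#' Indel frequency is `100 * base * prod(region multipliers) + N(0, sigma)`
#' clipped to `[0, 100]`, with multipliers 0.1 (seed, positions 5-10),
#' 0.5 (trunk, 11-22) and 0.9 (promiscuous, 23-27) by default, so seed
#' mismatches are most damaging — the ordering the off-target classifier
#' must recover. The per-record base activity is drawn uniform on
#' `[baseMin, baseMax]`.
#'
#' @param n number of records (>= 10).
#' @param seed integer seed.
#' @param seedMult,trunkMult,promMult region multipliers,
#'   `0 <= seedMult < trunkMult < promMult <= 1`.
#' @param sigma Gaussian noise sd on the percent scale (default 5).
#' @param baseMin,baseMax range of the per-record base activity.
#' @param maxMismatches maximum mismatches per record (default 6).
#' @return data.frame with columns `guide`, `target`, `indel_frequency`,
#'   `n_mismatches`.
#' @export
simulateMismatch <- function(n, seed = 1L, seedMult = 0.1, trunkMult = 0.5,
                             promMult = 0.9, sigma = 5, baseMin = 0.5,
                             baseMax = 1.0, maxMismatches = 6L) {
  stopifnot(isWholeNumber(n), n >= 10, sigma >= 0,
            0 <= seedMult, seedMult < trunkMult, trunkMult < promMult,
            promMult <= 1, maxMismatches >= 0, maxMismatches <= 23)
  regionMult <- function(pos) {
    ifelse(pos <= max(SEED_POSITIONS), seedMult,
           ifelse(pos <= max(TRUNK_POSITIONS), trunkMult, promMult))
  }
  withSeed(seed, {
    guides <- randomTarget27(n)
    base <- runif(n, baseMin, baseMax)
    nmm <- if (maxMismatches == 0L) rep(0L, n)
           else sample.int(maxMismatches, n, replace = TRUE)
    targets <- character(n)
    mult <- numeric(n)
    for (i in seq_len(n)) {
      ch <- strsplit(guides[i], "", fixed = TRUE)[[1]]
      if (nmm[i] > 0L) {
        pos <- sample(5:27, nmm[i])
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
        mult[i] <- prod(regionMult(pos))
      } else mult[i] <- 1
      targets[i] <- paste(ch, collapse = "")
    }
    freq <- pmin(100, pmax(0, 100 * base * mult + rnorm(n, 0, sigma)))
    data.frame(guide = guides, target = targets, indel_frequency = freq,
               n_mismatches = nmm)
  })
}

#' Simulate a genome with planted guide target sites
#'
#' Draws an i.i.d. uniform background sequence and plants copies of the
#' given 27-nt guides, each copy carrying an exact number of protospacer
#' substitutions, on random strands at non-overlapping positions. The PAM
#' is left intact so every planted copy is discoverable by the TTTN-N23
#' scan. Returns the sequence together with a truth table of planted loci.
#'
#' @param length genome length (>= 1000).
#' @param planted list of `list(guide = <27-nt string>, nCopies = ..,
#'   nMismatches = ..)` entries.
#' @param seed integer seed.
#' @param name sequence name.
#' @param maxTries placement retries before giving up.
#' @return list with `sequence` (named character) and `truth`
#'   ([GenomicRanges::GRanges] with metadata `guide`, `siteSequence`
#'   (PAM-first), `nMismatches`).
#' @export
simulateGenome <- function(length, planted = list(), seed = 1L,
                           name = "synth1", maxTries = 1000L) {
  stopifnot(isWholeNumber(length), length >= 1000)
  withSeed(seed, {
    chars <- sample(DNA_BASES, length, replace = TRUE)
    used <- logical(length)
    truth <- list()
    ti <- 0L
    for (spec in planted) {
      g <- toupper(spec$guide)
      stopifnot(nchar(g) == 27L, substr(g, 1, 3) == "TTT")
      for (copy in seq_len(spec$nCopies)) {
        site <- strsplit(g, "", fixed = TRUE)[[1]]
        if (spec$nMismatches > 0L) {
          pos <- sample(5:27, spec$nMismatches)
          for (p in pos) site[p] <- sample(setdiff(DNA_BASES, site[p]), 1)
        }
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          strand <- sample(c("+", "-"), 1)
          start <- sample.int(length - 26L, 1)
          span <- start:(start + 26L)
          if (any(used[span])) next
          ins <- if (strand == "+") site
                 else strsplit(reverseComplementStr(
                   paste(site, collapse = "")), "", fixed = TRUE)[[1]]
          chars[span] <- ins
          used[span] <- TRUE
          ti <- ti + 1L
          truth[[ti]] <- data.frame(
            start = start, strand = strand, guide = g,
            siteSequence = paste(site, collapse = ""),
            nMismatches = spec$nMismatches)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place a planted site without overlap; ",
               "increase the genome length")
      }
    }
    truthDf <- do.call(rbind, c(truth, list(data.frame(
      start = integer(), strand = character(), guide = character(),
      siteSequence = character(), nMismatches = integer()))))
    truthGr <- GRanges(rep(name, nrow(truthDf)),
                       IRanges(start = truthDf$start, width = 27L),
                       strand = truthDf$strand)
    mcols(truthGr)$guide <- truthDf$guide
    mcols(truthGr)$siteSequence <- truthDf$siteSequence
    mcols(truthGr)$nMismatches <- truthDf$nMismatches
    list(sequence = stats::setNames(paste(chars, collapse = ""), name),
         truth = truthGr)
  })
}
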