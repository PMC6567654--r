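#' K-mer category labels in fixed lexicographic order
#'
#' Row labels used by the order-k one-hot schemes: all 4^k k-mers over
#' {A,C,G,T} ordered lexicographically (AA, AC, AG, AT, CA, ... for k = 2).
#'
#' @param k k-mer order (1, 2 or 3).
#' @return character vector of length 4^k.
#' @export
#' @examples
#' kmerLabels(2)[1:5]
kmerLabels <- function(k) {
  stopifnot(isWholeNumber(k), k >= 1, k <= 3)
  labs <- DNA_BASES
  if (k > 1) for (i in 2:k)
    labs <- as.vector(t(outer(labs, DNA_BASES, paste0)))
  labs
}

#' Mismatch-type labels in fixed lexicographic order
#'
#' The 12 ordered guide-to-target substitutions: A>C, A>G, A>T, C>A, ...,
#' T>G, where `g>t` means the guide carries base g and the genomic site
#' base t at that position.
#'
#' @return character vector of length 12.
#' @export
mismatchLabels <- function() {
  unlist(lapply(DNA_BASES, function(g)
    paste0(g, ">", setdiff(DNA_BASES, g))))
}

## 4x4 lookup: row = guide code, col = target code, value = row index in the
## 12-type mismatch scheme (NA on the diagonal).
.mismatchRowLookup <- local({
  m <- matrix(NA_integer_, 4, 4)
  r <- 0L
  for (g in 1:4) for (t in setdiff(1:4, g)) {
    r <- r + 1L
    m[g, t] <- r
  }
  m
})

#' One-hot encode a DNA sequence with a sliding k-mer window
#'
#' Slides a window of k nucleotides along the sequence with step 1 and marks,
#' for each window position, the row of the observed k-mer. A 27-nt target
#' (4-nt TTTN PAM + 23-nt protospacer) yields a 16 x 26 matrix at k = 2,
#' 4 x 27 at k = 1 and 64 x 25 at k = 3. Every column sums to exactly 1.
#'
#' @param seq DNA string (A/C/G/T only), length >= k.
#' @param k window size (1, 2 or 3).
#' @return a [OneHotMatrix-class] with 4^k rows and `nchar(seq) - k + 1`
#'   columns; rows labelled by [kmerLabels()], columns by position.
#' @export
#' @examples
#' dim(encodeOrderK(strrep("A", 27), 2))   # 16 x 26
encodeOrderK <- function(seq, k = 2) {
  stopifnot(is.character(seq), length(seq) == 1L,
            isWholeNumber(k), k >= 1, k <= 3)
  L <- nchar(seq)
  if (L < k)
    stop(sprintf("sequence length %d is shorter than window size %d", L, k))
  codes <- dnaCodes(seq)
  ncols <- L - k + 1L
  ## lexicographic k-mer index, first base most significant
  idx <- codes[seq_len(ncols)] - 1L
  if (k > 1) for (j in 2:k)
    idx <- idx * 4L + (codes[j:(j + ncols - 1L)] - 1L)
  m <- matrix(0, nrow = 4L^k, ncol = ncols,
              dimnames = list(kmerLabels(k), seq_len(ncols)))
  m[cbind(idx + 1L, seq_len(ncols))] <- 1
  new("OneHotMatrix", m, scheme = paste0("order", k))
}

#' One-hot encode a guide/target mismatch pair
#'
#' Compares a 27-nt guide (intended target, PAM-first) with a 27-nt genomic
#' site position by position. Matched positions give all-zero columns; a
#' mismatch with guide base g and site base t sets a single 1 in the row for
#' the ordered substitution g>t. The matrix total therefore equals the
#' Hamming distance of the pair.
#'
#' @param guide,target 27-nt DNA strings (A/C/G/T).
#' @return a 12 x 27 [OneHotMatrix-class], rows labelled by
#'   [mismatchLabels()].
#' @export
#' @examples
#' sum(encodeMismatchPair(strrep("A", 27), strrep("A", 27)))  # 0
encodeMismatchPair <- function(guide, target) {
  stopifnot(is.character(guide), length(guide) == 1L,
            is.character(target), length(target) == 1L)
  if (nchar(guide) != nchar(target))
    stop(sprintf("guide (%d nt) and target (%d nt) must have equal length",
                 nchar(guide), nchar(target)))
  if (nchar(guide) != 27L)
    stop("guide and target must be 27 nt (TTTN PAM + 23-nt protospacer)")
  g <- dnaCodes(guide, "guide")
  t <- dnaCodes(target, "target")
  m <- matrix(0, nrow = 12L, ncol = 27L,
              dimnames = list(mismatchLabels(), seq_len(27L)))
  mm <- which(g != t)
  if (length(mm))
    m[cbind(.mismatchRowLookup[cbind(g[mm], t[mm])], mm)] <- 1
  new("OneHotMatrix", m, scheme = "mismatch")
}

#' Input-matrix columns covering a set of sequence positions
#'
#' In an order-k encoding, column j spans sequence positions j .. j+k-1, so
#' a sequence position p contributes to columns max(1, p-k+1) .. min(p, L-k+1).
#' This maps a position set (e.g. the seed region, positions 5-10) to the
#' encoding columns it touches — needed when reading heatmaps over order-2
#' inputs in sequence coordinates. The mismatch scheme is positional
#' (k = 1 behaviour).
#'
#' @param positions integer vector of 1-based sequence positions.
#' @param k encoding order (1, 2 or 3); use 1 for the mismatch scheme.
#' @param L sequence length (default 27).
#' @return sorted integer vector of column indices.
#' @export
#' @examples
#' positionColumns(5:10, k = 2)   # columns 4..10 of the 16 x 26 matrix
positionColumns <- function(positions, k = 2, L = 27L) {
  stopifnot(all(positions >= 1), all(positions <= L), k %in% 1:3)
  cols <- unlist(lapply(positions, function(p)
    max(1L, p - k + 1L):min(p, L - k + 1L)))
  sort(unique(cols))
}

#' Randomly permute the rows (categories) of a one-hot matrix
#'
#' Applies a seeded uniform random permutation to the category rows; column
#' sums and the multiset of rows are unchanged. Used to probe whether row
#' (category) order influences a downstream classifier. The permutation used
#' is attached as attribute `"permutation"` so it can be inverted with
#' `m[order(attr(p, "permutation")), ]`.
#'
#' @param m a [OneHotMatrix-class].
#' @param seed integer seed; the same seed always yields the same permutation.
#' @return a [OneHotMatrix-class] with permuted rows.
#' @export
permuteRows <- function(m, seed) {
  stopifnot(is(m, "OneHotMatrix"), isWholeNumber(seed))
  perm <- withSeed(seed, sample.int(nrow(m)))
  out <- new("OneHotMatrix", m@.Data[perm, , drop = FALSE],
             scheme = m@scheme)
  attr(out, "permutation") <- perm
  out
}

#' Extract the 40-nt context window around a 27-nt target site
#'
#' Returns the site in PAM-first orientation together with 7 nt upstream and
#' 6 nt downstream (upstream/downstream in the guide's own orientation).
#' Minus-strand sites are handled by reverse-complementing the sequence
#' before windowing.
#'
#' @param genome DNA string.
#' @param siteStart 0-based offset of the 27-nt site on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @return a 40-nt DNA string containing the 27-nt site at offset 7.
#' @export
extractContextWindow <- function(genome, siteStart, strand = "+") {
  stopifnot(is.character(genome), length(genome) == 1L,
            isWholeNumber(siteStart), strand %in% c("+", "-"))
  L <- nchar(genome)
  if (siteStart < 0 || siteStart + 27 > L)
    stop("27-nt site does not fit within the sequence")
  if (strand == "-") {
    return(extractContextWindow(reverseComplementStr(genome),
                                L - (siteStart + 27), "+"))
  }
  if (siteStart - 7 < 0 || siteStart + 33 > L)
    stop(sprintf(
      "context window [%d, %d) out of bounds for sequence of length %d",
      siteStart - 7, siteStart + 33, L))
  substr(genome, siteStart - 7 + 1, siteStart + 33)
}

#' Write a one-hot matrix as labelled TSV
#'
#' @param m a [OneHotMatrix-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeOneHot <- function(m, path) {
  stopifnot(is(m, "OneHotMatrix"))
  df <- data.frame(category = rownames(m), m@.Data, check.names = FALSE)
  colnames(df) <- c("category", paste0("pos", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
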