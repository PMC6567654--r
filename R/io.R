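#' Read a FASTA file of DNA sequences
#'
#' Wraps [Biostrings::readDNAStringSet()]: sequences are upper-cased,
#' description lines are split at the first whitespace, duplicate names and
#' empty files are errors, and only A/C/G/T/N are accepted (N-containing
#' windows are skipped later by [findCandidateSites()]).
#'
#' @param path FASTA file.
#' @return named uppercase character vector of sequences.
#' @export
readFastaFile <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop(sprintf("no sequences in '%s'", path))
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms))
    stop(sprintf("duplicate sequence name '%s' in '%s'",
                 nms[duplicated(nms)][1], path))
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("sequence '%s' contains IUPAC codes outside {A,C,G,T,N}",
                 nms[bad][1]))
  stats::setNames(seqs, nms)
}

#' Write sequences as FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeFastaFile <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

checkSeqColumn <- function(x, col, path) {
  x <- toupper(x)
  len <- nchar(x)
  bad <- which(len != 27L)
  if (length(bad))
    stop(sprintf("%s: row %d: %s must be 27 nt, got %d nt",
                 path, bad[1], col, len[bad[1]]))
  nonacgt <- grepl("[^ACGT]", x)
  if (any(nonacgt))
    stop(sprintf("%s: row %d: %s contains non-ACGT characters",
                 path, which(nonacgt)[1], col))
  x
}

#' Read a matched or mismatched guide dataset
#'
#' TSV with a header. `kind = "matched"` requires columns `sequence` and
#' `indel_frequency`; `kind = "mismatched"` requires `guide`, `target` and
#' `indel_frequency`. Sequences must be 27-nt A/C/G/T; frequencies must be
#' numeric percentages in `[0, 100]`. Violations are reported with their
#' row number.
#'
#' @param path TSV file.
#' @param kind `"matched"` or `"mismatched"`.
#' @return validated data.frame.
#' @export
readGuideDataset <- function(path, kind = c("matched", "mismatched")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = TRUE, sep = "\t", dec = ".",
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- if (kind == "matched") c("sequence", "indel_frequency")
          else c("guide", "target", "indel_frequency")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  freq <- suppressWarnings(as.numeric(df$indel_frequency))
  bad <- which(is.na(freq))
  if (length(bad))
    stop(sprintf("%s: row %d: non-numeric indel_frequency '%s'",
                 path, bad[1], df$indel_frequency[bad[1]]))
  out <- which(freq < 0 | freq > 100)
  if (length(out))
    stop(sprintf("%s: row %d: indel_frequency %s outside [0, 100]",
                 path, out[1], df$indel_frequency[out[1]]))
  df$indel_frequency <- freq
  if (kind == "matched") {
    df$sequence <- checkSeqColumn(df$sequence, "sequence", path)
    df[, need, drop = FALSE]
  } else {
    df$guide <- checkSeqColumn(df$guide, "guide", path)
    df$target <- checkSeqColumn(df$target, "target", path)
    df[, need, drop = FALSE]
  }
}

#' Write a guide dataset as TSV
#'
#' Inverse of [readGuideDataset()]: writes the columns the reader requires
#' (plus any extras present) with a header, tab separation and '.' decimals.
#'
#' @param records data.frame from [simulateOnTarget()],
#'   [simulateMismatch()] or [readGuideDataset()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGuideDataset <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation report or cutoff grid as TSV
#'
#' @param x a `cvReport` from [externalCV()] or the data.frame from
#'   [cutoffGrid()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeCvReport <- function(x, path) {
  df <- if (inherits(x, "cvReport"))
    data.frame(fold = seq_along(x$foldAucs), auc = x$foldAucs,
               size = x$foldSizes)
  else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC curve points as two-column TSV
#'
#' @param roc result of [rocAuc()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRocCurve <- function(roc, path) {
  write.table(roc$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
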