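#' @importFrom methods new validObject is slot
#' @importFrom stats cor rnorm runif predict sd
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverseComplementStr("TTTACCG")
reverseComplementStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run `expr` under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Integer codes 1..4 for A,C,G,T; stops naming the first offending position.
dnaCodes <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("non-ACGT character '%s' in %s at position %d",
                 chars[bad], what, bad))
  }
  codes
}

## Stable descending order by value (ties keep input order).
orderDesc <- function(x) order(-x, seq_along(x), method = "radix")

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
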