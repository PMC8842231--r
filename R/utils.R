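#' @import methods
#' @importFrom stats wilcox.test p.adjust runif rbinom rnorm rlnorm setNames
#' @importFrom utils adist read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character vectors
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## leftmost match start of `pattern` in each sequence of `subjects`
## (DNAStringSet), NA when absent
leftmost_match <- function(pattern, subjects, max.mismatch = 0L) {
  m <- Biostrings::vmatchPattern(pattern, subjects, max.mismatch = max.mismatch)
  st <- Biostrings::startIndex(m)
  vapply(st, function(v) if (length(v)) min(v) else NA_integer_, integer(1))
}

## all match starts per sequence, as a list of integer vectors
all_matches <- function(pattern, subjects, max.mismatch = 0L) {
  m <- Biostrings::vmatchPattern(pattern, subjects, max.mismatch = max.mismatch)
  Biostrings::startIndex(m)
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
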