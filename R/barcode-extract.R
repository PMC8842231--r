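## Barcode retrieval: internal-index demultiplexing, three-step adapter
## matching, and backbone read-through trimming. All operations are
## vectorised over reads; scalar wrappers exist for single-read use.

#' Demultiplex reads by internal sample index
#'
#' Internal indices sit at the 5' end of indel-PCR reads and are not removed
#' by the sequencer. A read is assigned to a sample iff exactly one index
#' matches its prefix within `max_mismatch` substitutions; assigned reads
#' have the index stripped.
#'
#' @param reads character vector (or DNAStringSet) of reads.
#' @param index_table named character vector: sample name -> index sequence.
#'   All indices must share one length and be pairwise separated by a
#'   Hamming distance greater than `2 * max_mismatch`.
#' @param max_mismatch substitutions tolerated in the index (default 1).
#' @return data.frame with columns `sample` (NA when unassigned) and `read`
#'   (index removed when assigned, untouched otherwise).
#' @export
demultiplex_index <- function(reads, index_table, max_mismatch = 1L) {
  reads <- as.character(reads)
  idx <- toupper(index_table)
  L <- unique(nchar(idx))
  if (length(L) != 1L)
    stop("configuration error: indices must all have the same length")
  if (length(idx) > 1L) {
    d <- adist(idx, idx, costs = list(ins = 100, del = 100, sub = 1))
    if (min(d[upper.tri(d)]) <= 2L * max_mismatch)
      stop("configuration error: index pair closer than 2*max_mismatch+1 (clashing indices)")
  }
  prefixes <- Biostrings::DNAStringSet(substr(reads, 1L, L))
  hit <- sapply(idx, function(ix)
    Biostrings::vcountPattern(ix, prefixes, max.mismatch = max_mismatch) > 0L)
  hit <- matrix(hit, nrow = length(reads))
  n_hit <- rowSums(hit)
  which_hit <- max.col(hit, ties.method = "first")
  sample <- ifelse(n_hit == 1L, names(idx)[which_hit], NA_character_)
  out_read <- ifelse(is.na(sample), reads, substr(reads, L + 1L, nchar(reads)))
  data.frame(sample = sample, read = out_read, stringsAsFactors = FALSE)
}

#' Extract reporter barcodes with the three-step adapter strategy
#'
#' Barcodes sit inside a constant cassette `adapter_5p {barcode} adapter_3p`.
#' Retrieval tries, in order: (1) `full` — the 5' arm is found and the 3' arm
#' sits at barcode distance 16 (then 15, then 17) downstream, recovering
#' shortened/lengthened barcodes; (2) `five_prime` — only the 5' arm is
#' found, the next 16 bp are taken; (3) `three_prime` — only the 3' arm is
#' found (with at least 16 bp before it), the preceding 16 bp are taken.
#' Reads failing all three are recorded with `step = "failed"`, never
#' raised as errors. Matching tolerates up to
#' `params$adapter_max_mismatches` substitutions in the 5' arm; arms of 5 bp
#' or less are always matched exactly. When an arm matches several
#' positions, the leftmost is used. The `remainder` is the read content
#' downstream of the 3' arm (empty when no downstream sequence exists).
#'
#' @param reads character vector (or DNAStringSet) of reads (internal index
#'   already removed).
#' @param spec a `reporter_spec`.
#' @param params a `pipeline_params`.
#' @return data.frame of class `extraction_result`: `read_id`, `barcode`
#'   (NA when failed), `step` (`full`/`five_prime`/`three_prime`/`failed`),
#'   `remainder`.
#' @export
extract_barcodes <- function(reads, spec, params = pipeline_params()) {
  ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
  reads <- as.character(reads)
  n <- length(reads)
  a5 <- spec$adapter_5p; a3 <- spec$adapter_3p
  n5 <- nchar(a5); n3 <- nchar(a3)
  mm5 <- if (n5 <= 5L) 0L else params$adapter_max_mismatches
  mm3 <- if (n3 <= 5L) 0L else params$adapter_max_mismatches
  min_len <- n5 + spec$barcode_len_range[1] + n3

  barcode <- rep(NA_character_, n)
  step <- rep("failed", n)
  remainder <- rep("", n)
  long <- nchar(reads) >= min_len
  if (any(long)) {
    sub <- Biostrings::DNAStringSet(reads[long])
    s5 <- leftmost_match(a5, sub, max.mismatch = mm5)
    rl <- nchar(reads[long])
    bstart <- s5 + n5                    # first barcode base (1-based)
    bc_l <- rep(NA_integer_, length(s5)) # matched barcode length (full step)
    ## try designed length first, then the tolerated shorter/longer ones
    for (Lb in c(spec$barcode_len_expected,
                 setdiff(seq(spec$barcode_len_range[1],
                             spec$barcode_len_range[2]),
                         spec$barcode_len_expected))) {
      cand <- !is.na(s5) & is.na(bc_l) & (bstart + Lb + n3 - 1L <= rl)
      if (mm3 == 0L) {
        ok <- cand & substr(reads[long], bstart + Lb,
                            bstart + Lb + n3 - 1L) == a3
      } else {
        ok <- cand
        w <- which(cand)
        if (length(w)) {
          arm <- Biostrings::DNAStringSet(
            substr(reads[long][w], bstart[w] + Lb, bstart[w] + Lb + n3 - 1L))
          ok[w] <- Biostrings::vcountPattern(a3, arm, max.mismatch = mm3) > 0L
          ok[setdiff(seq_along(ok), w)] <- FALSE
        }
      }
      ok[is.na(ok)] <- FALSE
      bc_l[ok] <- Lb
    }
    lstep <- rep("failed", length(s5))
    lbc <- rep(NA_character_, length(s5))
    lrem <- rep("", length(s5))

    full <- !is.na(bc_l)
    lstep[full] <- "full"
    lbc[full] <- substr(reads[long][full], bstart[full],
                        bstart[full] + bc_l[full] - 1L)
    rs <- bstart + ifelse(is.na(bc_l), NA_integer_, bc_l) + n3
    lrem[full] <- substr(reads[long][full], rs[full], rl[full])

    fp <- !full & !is.na(s5) &
      (bstart + spec$barcode_len_expected - 1L <= rl)
    lstep[fp] <- "five_prime"
    lbc[fp] <- substr(reads[long][fp], bstart[fp],
                      bstart[fp] + spec$barcode_len_expected - 1L)
    ## assume the designed structure downstream of the unmatched 3' arm
    rs2 <- bstart + spec$barcode_len_expected + n3
    lrem[fp] <- substr(reads[long][fp], rs2[fp], rl[fp])

    tp_cand <- !full & !fp & is.na(s5)
    if (any(tp_cand)) {
      m3 <- all_matches(a3, sub[tp_cand], max.mismatch = mm3)
      bexp <- spec$barcode_len_expected
      s3 <- vapply(m3, function(v) {
        v <- v[v > bexp]
        if (length(v)) min(v) else NA_integer_
      }, integer(1))
      w <- which(tp_cand)[!is.na(s3)]
      s3 <- s3[!is.na(s3)]
      lstep[w] <- "three_prime"
      lbc[w] <- substr(reads[long][w], s3 - bexp, s3 - 1L)
      lrem[w] <- substr(reads[long][w], s3 + n3, rl[w])
    }
    barcode[long] <- lbc
    step[long] <- lstep
    remainder[long] <- lrem
  }
  out <- data.frame(read_id = ids, barcode = barcode, step = step,
                    remainder = remainder, stringsAsFactors = FALSE)
  class(out) <- c("extraction_result", "data.frame")
  out
}

#' Extract the barcode of a single read
#'
#' Scalar convenience wrapper around [extract_barcodes()].
#'
#' @inheritParams extract_barcodes
#' @param read a single read sequence.
#' @return one-row `extraction_result` data.frame.
#' @export
extract_barcode <- function(read, spec, params = pipeline_params()) {
  extract_barcodes(setNames(read, "read_1"), spec, params)
}

#' Trim plasmid-backbone read-through
#'
#' When a deletion shortens the amplicon, sequencing continues into the
#' plasmid backbone and the reverse complements of the constant cassette
#' patterns appear at the 3' end of the remainder. The remainder is
#' truncated immediately before the leftmost occurrence of any such
#' pattern (the 5' adapter arm and, when configured, the inverse-PCR
#' read-2 constant), tolerating `params$adapter_max_mismatches`
#' substitutions.
#'
#' @param remainder character vector of remainders.
#' @param spec a `reporter_spec`.
#' @param params a `pipeline_params`.
#' @return character vector of trimmed remainders; attribute `"n_trimmed"`
#'   counts the reads that were truncated.
#' @export
trim_readthrough <- function(remainder, spec, params = pipeline_params()) {
  pats <- revcomp(spec$adapter_5p)
  if (nzchar(spec$ipcr_read2_constant))
    pats <- c(pats, revcomp(spec$ipcr_read2_constant))
  cut_at <- rep(NA_integer_, length(remainder))
  nonempty <- nzchar(remainder)
  if (any(nonempty)) {
    sub <- Biostrings::DNAStringSet(remainder[nonempty])
    for (p in pats) {
      s <- leftmost_match(p, sub, max.mismatch = params$adapter_max_mismatches)
      cur <- cut_at[nonempty]
      cut_at[nonempty] <- ifelse(is.na(cur), s, pmin(cur, s, na.rm = TRUE))
    }
  }
  out <- ifelse(is.na(cut_at), remainder, substr(remainder, 1L, cut_at - 1L))
  attr(out, "n_trimmed") <- sum(!is.na(cut_at))
  out
}

#' Extract barcodes and genomic fragments from inverse-PCR read pairs
#'
#' Barcode retrieval runs on read 1 exactly as for indel-PCR reads. Read 2
#' must begin with the transposon-edge constant (`spec$ipcr_read2_constant`,
#' matched at the 5' end within `params$adapter_max_mismatches`
#' substitutions); its genomic portion is the sequence beyond that
#' constant. Pairs failing either check are recorded as failed.
#'
#' @param read1,read2 character vectors of mate sequences (equal length).
#' @param spec a `reporter_spec`.
#' @param params a `pipeline_params`.
#' @return data.frame: `read_id`, `barcode`, `step`, `genomic` (read-2
#'   genomic portion, NA when the pair failed), `pass`.
#' @export
extract_ipcr_pair <- function(read1, read2, spec, params = pipeline_params()) {
  stopifnot(length(read1) == length(read2))
  ex <- extract_barcodes(read1, spec, params)
  const <- spec$ipcr_read2_constant
  if (!nzchar(const))
    stop("spec$ipcr_read2_constant must be set for inverse-PCR extraction")
  r2 <- as.character(read2)
  head2 <- Biostrings::DNAStringSet(substr(r2, 1L, nchar(const)))
  ok2 <- Biostrings::vcountPattern(const, head2,
    max.mismatch = params$adapter_max_mismatches) > 0L &
    nchar(r2) >= nchar(const)
  pass <- ex$step != "failed" & ok2
  data.frame(read_id = ex$read_id,
             barcode = ifelse(pass, ex$barcode, NA_character_),
             step = ifelse(ok2, ex$step, "failed"),
             genomic = ifelse(pass, substr(r2, nchar(const) + 1L, nchar(r2)),
                              NA_character_),
             pass = pass,
             stringsAsFactors = FALSE)
}

#' Per-sample extraction statistics
#'
#' @param extraction an `extraction_result` data.frame.
#' @param n_unassigned reads dropped at index demultiplexing.
#' @param n_trimmed reads whose remainder was read-through trimmed.
#' @return one-row data.frame: total, full, five_prime, three_prime, failed,
#'   readthrough_trimmed, index_unassigned. `total` always equals the sum of
#'   the step counters.
#' @export
extraction_stats <- function(extraction, n_unassigned = 0L, n_trimmed = 0L) {
  tab <- table(factor(extraction$step,
                      levels = c("full", "five_prime", "three_prime", "failed")))
  data.frame(total = nrow(extraction),
             full = as.integer(tab[["full"]]),
             five_prime = as.integer(tab[["five_prime"]]),
             three_prime = as.integer(tab[["three_prime"]]),
             failed = as.integer(tab[["failed"]]),
             readthrough_trimmed = as.integer(n_trimmed),
             index_unassigned = as.integer(n_unassigned))
}
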