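## Per-read repair-outcome calling: recognition-sequence matching,
## spacer-displacement indel sizing, the call taxonomy, and the optional
## pairwise-alignment mode that resolves exact scars and microhomologies.

#' Match remainders against named recognition sequences
#'
#' Exact substring search of every configured recognition sequence (the
#' wild-type window and any designed mutation products) in each remainder;
#' when several match, the longest sequence wins. Matching is exact by
#' design: recognition sequences define calls, and reads that fail them are
#' routed to size-based calls instead.
#'
#' @param remainder character vector of adapter-trimmed remainders.
#' @param spec a `reporter_spec`.
#' @return character vector of recognition names (NA where none matched).
#' @export
match_recognition <- function(remainder, spec) {
  rs <- spec$recognition_seqs[order(-nchar(spec$recognition_seqs))]
  out <- rep(NA_character_, length(remainder))
  nonempty <- which(nzchar(remainder) & is.na(out))
  if (!length(nonempty)) return(out)
  sub <- Biostrings::DNAStringSet(remainder)
  for (i in seq_along(rs)) {
    todo <- which(is.na(out) & nzchar(remainder))
    if (!length(todo)) break
    hit <- Biostrings::vcountPattern(rs[[i]], sub[todo]) > 0L
    out[todo[hit]] <- names(rs)[i]
  }
  out
}

#' Indel size from spacer displacement
#'
#' Seven (in general, any number of) unique marker sequences sit downstream
#' of the cut site at known wild-type offsets. Spacers are scanned in
#' order; for the first spacer found in a remainder, the occurrence nearest
#' its expected offset is used and the indel size is its observed offset
#' minus the expected one. Because any intact spacer suffices, the size is
#' robust to sequencing errors or mutations downstream of the first intact
#' spacer. Returns NA when no spacer is found.
#'
#' @param remainder character vector of adapter-trimmed remainders.
#' @param spec a `reporter_spec`.
#' @return integer vector of indel sizes (negative = deletion, positive =
#'   insertion, NA = no spacer found).
#' @export
indel_size_by_spacers <- function(remainder, spec) {
  out <- rep(NA_integer_, length(remainder))
  nonempty <- nzchar(remainder)
  if (!any(nonempty)) return(out)
  sub <- Biostrings::DNAStringSet(remainder[nonempty])
  res <- rep(NA_integer_, length(sub))
  for (i in seq_len(nrow(spec$spacers))) {
    todo <- which(is.na(res))
    if (!length(todo)) break
    starts <- all_matches(spec$spacers$seq[i], sub[todo])
    exp0 <- spec$spacers$offset[i]
    found <- lengths(starts) > 0L
    res[todo[found]] <- vapply(starts[found], function(v) {
      obs0 <- v - 1L                      # 0-based observed offsets
      obs0[which.min(abs(obs0 - exp0))] - exp0
    }, integer(1))
  }
  out[nonempty] <- res
  out
}

#' Classify reads into the repair-call taxonomy
#'
#' Each read receives exactly one call. When a recognition sequence
#' matches, the call is its name (`wt` for the wild-type window). Otherwise
#' the call follows the spacer-derived indel size: `del` (< 0), `ins`
#' (> 0) or `wt_point_mut` (= 0, i.e. no net change but a broken
#' recognition window). When neither a recognition sequence nor an indel
#' size is available the call is `not_clear`. The indel size is computed
#' and reported even for recognition-named calls, so a `wt` call can carry
#' a non-zero size (a technical artefact or a mutation away from the cut).
#'
#' @param remainder character vector of adapter-trimmed (and read-through
#'   trimmed) remainders.
#' @param spec a `reporter_spec`.
#' @return data.frame: `call`, `indel_size` (NA when not computable).
#' @export
classify_reads <- function(remainder, spec) {
  recog <- match_recognition(remainder, spec)
  size <- indel_size_by_spacers(remainder, spec)
  call <- ifelse(!is.na(recog), recog,
          ifelse(!is.na(size),
                 ifelse(size < 0L, "del", ifelse(size > 0L, "ins", "wt_point_mut")),
                 "not_clear"))
  data.frame(call = call, indel_size = size, stringsAsFactors = FALSE)
}

#' Count repair scars per barcode
#'
#' Groups calls into the four-column count table: barcode, mutation call,
#' indel size, number of reads. Row order is deterministic (barcode, call,
#' indel size); the total of the `reads` column always equals the number of
#' input calls.
#'
#' @param barcode character vector of (genuine) barcodes, parallel to
#'   `calls`.
#' @param calls data.frame from [classify_reads()].
#' @return data.frame of class `scar_count`: `barcode`, `call`,
#'   `indel_size`, `reads`.
#' @export
count_scars <- function(barcode, calls) {
  if (length(barcode) == 0L) {
    out <- data.frame(barcode = character(0), call = character(0),
                      indel_size = integer(0), reads = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("scar_count", "data.frame")
    return(out)
  }
  key <- paste(barcode, calls$call, calls$indel_size, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    barcode = vapply(parts, `[`, character(1), 1L),
    call = vapply(parts, `[`, character(1), 2L),
    indel_size = suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 3L))),
    reads = as.integer(tab),
    stringsAsFactors = FALSE)
  out <- out[order(out$barcode, out$call, out$indel_size), ]
  rownames(out) <- NULL
  class(out) <- c("scar_count", "data.frame")
  out
}

#' Resolve exact scars by pairwise alignment
#'
#' The slower, finer-grained alternative to spacer sizing: each remainder
#' is globally aligned to the wild-type amplicon (the pattern is aligned
#' end to end, the subject locally, so reads truncated by the sequencer do
#' not penalise the alignment). Both sequences are prefixed with a fixed
#' anchor so the alignment is pinned at the amplicon start — otherwise the
#' free subject window could absorb a large deletion by sliding instead of
#' opening a gap. Contiguous gap runs give the deletion interval and/or
#' inserted sequence; the net indel size is insertions minus deletions.
#' Deletions are left-aligned before the microhomology is computed, the
#' convention under which the ambiguity of an MMEJ deletion equals the
#' length of its flanking repeat. Alignments below `min_identity` percent
#' identity yield an absent detail row (the read falls back to
#' `not_clear`).
#'
#' Scoring defaults (+1 match, -4 mismatch, 3 gap opening, 0.25 gap
#' extension) keep long deletion gaps cheaper than the mismatch runs they
#' would otherwise be traded for, while a single substitution error is
#' still absorbed as a mismatch rather than an indel pair.
#'
#' @param remainder character vector of adapter/read-through-trimmed
#'   remainders.
#' @param spec a `reporter_spec`.
#' @param min_identity minimum percent identity (default 50).
#' @param match,mismatch,gap_opening,gap_extension alignment scores.
#' @return data.frame: `aligned`, `net_size`, `del_start` (0-based amplicon
#'   offset), `del_width`, `ins_seq`, `microhomology_len`, `identity`.
#' @export
align_scar <- function(remainder, spec, min_identity = 50,
                       match = 1, mismatch = -4,
                       gap_opening = 3, gap_extension = 0.25) {
  n <- length(remainder)
  out <- data.frame(aligned = rep(FALSE, n), net_size = NA_integer_,
                    del_start = NA_integer_, del_width = NA_integer_,
                    ins_seq = NA_character_, microhomology_len = NA_integer_,
                    identity = NA_real_, stringsAsFactors = FALSE)
  ok <- which(nzchar(remainder))
  if (!length(ok)) return(out)
  anchor <- "GTTGACCTAGGCGCGCCTAC"
  A <- nchar(anchor)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(paste0(anchor, remainder[ok])),
    Biostrings::DNAString(paste0(anchor, spec$wt_amplicon)),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  idy <- Biostrings::pid(pa)
  dels <- Biostrings::deletion(pa)    # gaps in the read, subject coordinates
  inss <- Biostrings::insertion(pa)   # extra read bases, pattern coordinates
  wt <- spec$wt_amplicon
  for (k in seq_along(ok)) {
    i <- ok[k]
    out$identity[i] <- idy[k]
    if (idy[k] < min_identity) next
    d <- dels[[k]]; ins <- inss[[k]]
    del_w <- sum(IRanges::width(d))
    ins_w <- sum(IRanges::width(ins))
    out$aligned[i] <- TRUE
    out$net_size[i] <- ins_w - del_w
    if (length(d) == 1L && length(ins) == 0L &&
        IRanges::start(d) > A) {
      ## translate from anchored-subject to amplicon coordinates
      la <- left_align_deletion(wt, IRanges::start(d) - A, IRanges::end(d) - A)
      out$del_start[i] <- la$start - 1L   # 0-based amplicon offset
      out$del_width[i] <- la$end - la$start + 1L
      out$microhomology_len[i] <- microhomology_length(wt, la$start, la$end)
    } else if (length(ins) == 1L && length(d) == 0L &&
               IRanges::start(ins) > A) {
      out$ins_seq[i] <- substr(remainder[i], IRanges::start(ins) - A,
                               IRanges::end(ins) - A)
      out$microhomology_len[i] <- 0L
    } else if (length(d) == 0L && length(ins) == 0L) {
      out$microhomology_len[i] <- 0L
    }
  }
  out
}

## shift a deletion interval (1-based, inclusive) left while the base before
## it equals the base at its end — the left-aligned representation
left_align_deletion <- function(wt, s, e) {
  while (s > 1L && substr(wt, s - 1L, s - 1L) == substr(wt, e, e)) {
    s <- s - 1L; e <- e - 1L
  }
  list(start = s, end = e)
}

## longest m such that the first m deleted bases equal the m bases retained
## just after the deletion: the flanking-repeat (microhomology) length
microhomology_length <- function(wt, s, e) {
  m <- 0L
  wlen <- nchar(wt)
  width <- e - s + 1L
  while (m < width && e + 1L + m <= wlen &&
         substr(wt, s + m, s + m) == substr(wt, e + 1L + m, e + 1L + m)) {
    m <- m + 1L
  }
  m
}

#' Write a scar count table as TSV
#'
#' @param counts a `scar_count` data.frame.
#' @param path output path (conventionally ending in `.count`).
#' @return `path`, invisibly.
#' @export
write_scar_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
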