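## Integration-site mapping from inverse-PCR alignments: SAM input,
## chimera-aware soft-clip triage with exact realignment, per-barcode
## location aggregation, and trustworthiness filters.

#' Read barcode-tagged alignments from SAM/BAM
#'
#' Converts SAM to BAM via Rsamtools when needed and extracts the fields the
#' mapping stage consumes. The reporter barcode is taken from a SAM tag
#' (default `BC`) or parsed from the read name (`barcode_in = "qname"`,
#' expecting `<id>_<barcode>`). The leading soft-clip is reported relative
#' to the read's 5' end: the first CIGAR operation for forward alignments,
#' the last for reverse ones, with the clipped sequence returned in read
#' orientation.
#'
#' @param path SAM or BAM file.
#' @param barcode_in `"tag"` (default) or `"qname"`.
#' @param tag SAM tag holding the barcode when `barcode_in = "tag"`.
#' @return data.frame of aligned reads: `read_id`, `barcode`, `mate`
#'   (`r1`/`r2`), `chrom`, `pos` (1-based leftmost), `strand`, `mapq`,
#'   `ref_len`, `leading_softclip_len`, `clipped_seq`.
#' @export
read_alignments <- function(path, barcode_in = c("tag", "qname"), tag = "BC") {
  barcode_in <- match.arg(barcode_in)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  p <- Rsamtools::ScanBamParam(what = what,
                               tag = if (barcode_in == "tag") tag else character(0))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  cig <- x$cigar[keep]
  strand <- as.character(x$strand)[keep]
  seqs <- as.character(x$seq)[keep]
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  first_op <- vapply(ops, function(o) o[1], character(1))
  last_op <- vapply(ops, function(o) o[length(o)], character(1))
  first_len <- vapply(lens, function(l) l[1], integer(1))
  last_len <- vapply(lens, function(l) l[length(l)], integer(1))
  lead <- ifelse(strand == "-",
                 ifelse(last_op == "S", last_len, 0L),
                 ifelse(first_op == "S", first_len, 0L))
  clipped <- rep(NA_character_, length(cig))
  wplus <- which(strand != "-" & lead > 0L)
  clipped[wplus] <- substr(seqs[wplus], 1L, lead[wplus])
  wminus <- which(strand == "-" & lead > 0L)
  if (length(wminus))
    clipped[wminus] <- revcomp(substr(seqs[wminus],
                                      nchar(seqs[wminus]) - lead[wminus] + 1L,
                                      nchar(seqs[wminus])))
  barcode <- if (barcode_in == "tag") {
    as.character(x$tag[[tag]][keep])
  } else {
    sub(".*_", "", x$qname[keep])
  }
  flag <- x$flag[keep]
  data.frame(
    read_id = x$qname[keep],
    barcode = barcode,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, "r1",
                  ifelse(bitwAnd(flag, 128L) > 0L, "r2", "r1")),
    chrom = as.character(x$rname)[keep],
    pos = x$pos[keep],
    strand = strand,
    mapq = x$mapq[keep],
    ref_len = GenomicAlignments::cigarWidthAlongReferenceSpace(cig),
    leading_softclip_len = lead,
    clipped_seq = clipped,
    stringsAsFactors = FALSE)
}

#' Triage transposon-edge reads by 5' soft-clip
#'
#' Reads entering the genome from the transposon edge should align from
#' their very first base; a 5' soft-clip signals a circular-ligation
#' chimera. Reads with no leading clip are kept; clips of up to `threshold`
#' bp are discarded; clips longer than `threshold` bp are routed to
#' realignment of the clipped sequence, which holds the genomic DNA that
#' actually flanks the reporter.
#'
#' @param reads data.frame of aligned reads (see [read_alignments()]).
#' @param threshold soft-clip length above which the clipped sequence is
#'   realigned (default 16 bp).
#' @return the input with an added `triage` column
#'   (`keep`/`discard`/`realign`).
#' @export
triage_softclip <- function(reads, threshold = 16L) {
  lead <- reads$leading_softclip_len
  triage <- ifelse(lead == 0L, "keep",
                   ifelse(lead <= threshold, "discard", "realign"))
  bad <- triage == "realign" &
    (is.na(reads$clipped_seq) | !nzchar(reads$clipped_seq))
  if (any(bad))
    stop("realignment requested but clipped sequence absent for read(s): ",
         paste(head(reads$read_id[bad], 5L), collapse = ", "))
  reads$triage <- triage
  reads
}

#' Realign soft-clipped chimera fragments
#'
#' Runs the exact-match mini-genome aligner on the clipped sequences of
#' reads triaged `realign` and returns them as ordinary aligned reads at
#' their new coordinates, so they re-enter location aggregation like any
#' other read. Ambiguous or unmatched fragments are dropped.
#'
#' @param reads triaged data.frame (see [triage_softclip()]).
#' @param genome named character vector of chromosome sequences.
#' @param mapq mapping quality assigned to unique exact rehits.
#' @return data.frame of realigned reads in the same shape as the input.
#' @export
realign_clipped <- function(reads, genome, mapq = 42L) {
  todo <- reads[reads$triage == "realign", , drop = FALSE]
  if (nrow(todo) == 0L) return(todo)
  aln <- naive_align(todo$clipped_seq, genome, mapq = mapq)
  ok <- !is.na(aln$chrom)
  out <- todo[ok, , drop = FALSE]
  out$chrom <- aln$chrom[ok]
  out$pos <- aln$pos[ok]
  out$strand <- aln$strand[ok]
  out$mapq <- aln$mapq[ok]
  out$ref_len <- aln$ref_len[ok]
  out$leading_softclip_len <- 0L
  out$clipped_seq <- NA_character_
  out$triage <- "keep"
  rownames(out) <- NULL
  out
}

## strand-aware junction coordinate: the genomic base adjacent to the
## transposon edge (leftmost aligned base on +, rightmost on -)
junction_pos <- function(pos, strand, ref_len) {
  ifelse(strand == "-", pos + ref_len - 1L, pos)
}

#' Aggregate aligned reads into per-barcode top-2 locations
#'
#' Reads (already soft-clip triaged and barcode-resolved) are grouped by
#' barcode and by location key — chromosome, strand and junction position,
#' with positions within a +/- `collapse_window` bp window collapsed to one
#' location to absorb end jitter. The two locations with most supporting
#' reads are reported with read counts and mapping-quality sums; ties are
#' broken deterministically by (count, mapq sum, chrom, pos).
#'
#' @param reads data.frame of aligned reads with `triage == "keep"` rows
#'   used (rows without a `triage` column are all used).
#' @param collapse_window positions within this distance of a location
#'   group's start are merged (default 2 bp).
#' @return data.frame of class `mapping_table`: per barcode `chrom1`,
#'   `pos1`, `strand1`, `reads1`, `mapq_sum1`, the same for the secondary
#'   location (NA when absent) and `total_reads`.
#' @export
aggregate_locations <- function(reads, collapse_window = 2L) {
  if (!is.null(reads$triage)) reads <- reads[reads$triage == "keep", , drop = FALSE]
  reads <- reads[!is.na(reads$barcode) & !is.na(reads$chrom), , drop = FALSE]
  empty <- data.frame(barcode = character(0), chrom1 = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      reads1 = integer(0), mapq_sum1 = numeric(0),
                      chrom2 = character(0), pos2 = integer(0),
                      strand2 = character(0), reads2 = integer(0),
                      mapq_sum2 = numeric(0), total_reads = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) { class(empty) <- c("mapping_table", "data.frame"); return(empty) }
  reads$jpos <- junction_pos(reads$pos, reads$strand, reads$ref_len)
  rows <- lapply(split(reads, reads$barcode), function(g) {
    locs <- do.call(rbind, lapply(split(g, paste(g$chrom, g$strand)), function(h) {
      o <- order(h$jpos)
      h <- h[o, , drop = FALSE]
      ## greedy grouping: new group when the position exceeds the group's
      ## first position by more than the window
      grp <- integer(nrow(h)); cur <- 0L; anchor <- -Inf
      for (i in seq_len(nrow(h))) {
        if (h$jpos[i] - anchor > collapse_window) { cur <- cur + 1L; anchor <- h$jpos[i] }
        grp[i] <- cur
      }
      do.call(rbind, lapply(split(h, grp), function(k) {
        tab <- sort(table(k$jpos), decreasing = TRUE)
        rep_pos <- as.integer(names(tab)[1])
        data.frame(chrom = k$chrom[1], pos = rep_pos, strand = k$strand[1],
                   reads = nrow(k), mapq_sum = sum(k$mapq),
                   stringsAsFactors = FALSE)
      }))
    }))
    locs <- locs[order(-locs$reads, -locs$mapq_sum, locs$chrom, locs$pos), ,
                 drop = FALSE]
    top <- locs[1, ]
    sec <- if (nrow(locs) >= 2L) locs[2, ] else
      data.frame(chrom = NA_character_, pos = NA_integer_,
                 strand = NA_character_, reads = NA_integer_,
                 mapq_sum = NA_real_, stringsAsFactors = FALSE)
    data.frame(barcode = g$barcode[1],
               chrom1 = top$chrom, pos1 = top$pos, strand1 = top$strand,
               reads1 = top$reads, mapq_sum1 = top$mapq_sum,
               chrom2 = sec$chrom, pos2 = sec$pos, strand2 = sec$strand,
               reads2 = sec$reads, mapq_sum2 = sec$mapq_sum,
               total_reads = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mapping_table", "data.frame")
  out
}

#' Filter barcodes to trustworthy integration sites
#'
#' A barcode passes iff its primary location is supported by at least
#' `min_ipcr_reads` reads with an average mapping quality above
#' `min_avg_mapq`, holds at least `min_primary_frac` of the barcode's total
#' reads, and no secondary location holds more than `max_secondary_frac` of
#' them (a missing secondary location counts as zero reads). Failing
#' barcodes carry every violated reason.
#'
#' @param table a `mapping_table`.
#' @param params a `pipeline_params`.
#' @return data.frame of integration calls: `barcode`, `chrom`, `pos`,
#'   `strand`, `status` (`pass`/`fail`), `reasons` (comma-separated codes:
#'   `min_reads`, `low_mapq`, `primary_frac`, `secondary_frac`).
#' @export
filter_locations <- function(table, params = pipeline_params()) {
  reads2 <- ifelse(is.na(table$reads2), 0L, table$reads2)
  ok_reads <- table$reads1 >= params$min_ipcr_reads
  ok_mapq <- (table$mapq_sum1 / table$reads1) > params$min_avg_mapq
  ok_prim <- (table$reads1 / table$total_reads) >= params$min_primary_frac
  ok_sec <- (reads2 / table$total_reads) <= params$max_secondary_frac
  reasons <- mapply(function(a, b, c, d) {
    paste(c(if (!a) "min_reads", if (!b) "low_mapq",
            if (!c) "primary_frac", if (!d) "secondary_frac"), collapse = ",")
  }, ok_reads, ok_mapq, ok_prim, ok_sec)
  data.frame(barcode = table$barcode,
             chrom = table$chrom1, pos = table$pos1, strand = table$strand1,
             status = ifelse(ok_reads & ok_mapq & ok_prim & ok_sec,
                             "pass", "fail"),
             reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Write a mapping table with its integration calls as TSV
#'
#' Coordinates are 1-based, as stated in the column names.
#'
#' @param table a `mapping_table`.
#' @param calls output of [filter_locations()] for the same table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(table, calls, path) {
  stopifnot(identical(table$barcode, calls$barcode))
  out <- data.frame(
    barcode = table$barcode,
    chrom = table$chrom1, start_1based = table$pos1, end_1based = table$pos1,
    strand = table$strand1, reads = table$reads1, mapq_sum = table$mapq_sum1,
    chrom2 = table$chrom2, start2_1based = table$pos2, reads2 = table$reads2,
    mapq_sum2 = table$mapq_sum2, total_reads = table$total_reads,
    status = calls$status, reasons = calls$reasons,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
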