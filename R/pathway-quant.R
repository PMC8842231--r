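## Downstream quantification: QC filtering, abundance-based cell estimates,
## replicate normalization, pathway classification and the MMEJ:NHEJ balance.

#' Pathway classification rules
#'
#' Signature outcomes of the assayed cut site: the -7 bp deletion flanked by
#' a 3 bp microhomology is the prominent MMEJ product and the +1 bp
#' insertion the prominent NHEJ product. Further known microhomology
#' deletions at this site (-14 bp with 3 bp and -22 bp with 6 bp
#' microhomology) are carried along for detail-mode classification.
#'
#' @param mmej_signatures data.frame with columns `indel_size` and `mh_len`
#'   (NA = any microhomology in count mode).
#' @param nhej_signatures integer vector of NHEJ indel sizes.
#' @param extra_mmej data.frame of additional known microhomology deletions.
#' @return object of class `pathway_rules`.
#' @export
pathway_rules <- function(mmej_signatures = data.frame(indel_size = -7L,
                                                       mh_len = 3L),
                          nhej_signatures = 1L,
                          extra_mmej = data.frame(indel_size = c(-14L, -22L),
                                                  mh_len = c(3L, 6L))) {
  overlap <- intersect(mmej_signatures$indel_size, nhej_signatures)
  if (length(overlap))
    stop("MMEJ and NHEJ signature sizes must be disjoint: ",
         paste(overlap, collapse = ", "))
  structure(list(mmej_signatures = mmej_signatures,
                 nhej_signatures = as.integer(nhej_signatures),
                 extra_mmej = extra_mmej),
            class = "pathway_rules")
}

#' Remove unresolvable calls from a scar count table
#'
#' Reads that failed both the recognition search and the indel-size
#' calculation (`not_clear`) carry no repair information and are removed
#' before quantification. The removed read fraction is reported via message
#' and as attribute `"removed_frac"` for comparison against historical
#' levels.
#'
#' @param counts a `scar_count` data.frame.
#' @return the table without `not_clear` rows.
#' @export
filter_not_clear <- function(counts) {
  total <- sum(counts$reads)
  drop <- counts$call == "not_clear"
  removed <- sum(counts$reads[drop])
  out <- counts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  frac <- if (total > 0) removed / total else 0
  message(sprintf("filter_not_clear: removed %d of %d reads (%.1f%%)",
                  removed, total, 100 * frac))
  attr(out, "removed_frac") <- frac
  class(out) <- c("scar_count", "data.frame")
  out
}

#' Estimate per-barcode cell representation
#'
#' In a reporter pool each barcode is carried by a limited number of cells.
#' Assuming `total_cells_assumed` cells per experiment with
#' `mean_barcodes_per_cell` barcodes each, a barcode's cell number is
#' estimated as its read count summed over all mutation calls, divided by
#' the experiment's total count, times the product of the two assumptions
#' (600,000 under the defaults). Barcodes below `min_cells` estimated cells
#' are flagged as not kept.
#'
#' @param counts a `scar_count` data.frame (non-empty).
#' @param params a `pipeline_params`.
#' @return data.frame: `barcode`, `estimated_cells`, `kept`. Estimates sum
#'   to `total_cells_assumed * mean_barcodes_per_cell` across barcodes.
#' @export
estimate_cells <- function(counts, params = pipeline_params()) {
  if (nrow(counts) == 0L || sum(counts$reads) == 0L)
    stop("counts must contain at least one read")
  per_bc <- tapply(counts$reads, counts$barcode, sum)
  total <- sum(counts$reads)
  est <- as.numeric(per_bc) / total *
    params$total_cells_assumed * params$mean_barcodes_per_cell
  data.frame(barcode = names(per_bc),
             estimated_cells = est,
             kept = est >= params$min_cells,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize scar counts across biological replicates
#'
#' Each replicate is scaled to counts per million of its library total,
#' replicates are averaged per (barcode, call, indel size) — a combination
#' absent from a replicate contributes zero — and indel-type proportions
#' are computed per barcode on the averaged values. Depth differences
#' between replicates therefore cancel exactly. Replicates with a zero
#' total are excluded with a warning.
#'
#' @param replicate_counts list of `scar_count` data.frames.
#' @return data.frame: `barcode`, `call`, `indel_size`, `mean_cpm`,
#'   `proportion` (of the barcode's averaged total).
#' @export
normalize_replicates <- function(replicate_counts) {
  if (!length(replicate_counts)) stop("at least one replicate is required")
  totals <- vapply(replicate_counts, function(x) sum(x$reads), numeric(1))
  if (any(totals == 0)) {
    warning(sum(totals == 0), " replicate(s) with zero total excluded")
    replicate_counts <- replicate_counts[totals > 0]
    totals <- totals[totals > 0]
    if (!length(replicate_counts)) stop("no replicate with nonzero total")
  }
  n_rep <- length(replicate_counts)
  long <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    x <- replicate_counts[[i]]
    data.frame(barcode = x$barcode, call = x$call, indel_size = x$indel_size,
               cpm = x$reads / totals[i] * 1e6, stringsAsFactors = FALSE)
  }))
  key <- paste(long$barcode, long$call, long$indel_size, sep = "\r")
  summed <- tapply(long$cpm, key, sum)
  parts <- strsplit(names(summed), "\r", fixed = TRUE)
  out <- data.frame(
    barcode = vapply(parts, `[`, character(1), 1L),
    call = vapply(parts, `[`, character(1), 2L),
    indel_size = suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 3L))),
    mean_cpm = as.numeric(summed) / n_rep,
    stringsAsFactors = FALSE)
  bc_tot <- tapply(out$mean_cpm, out$barcode, sum)
  out$proportion <- out$mean_cpm / as.numeric(bc_tot[out$barcode])
  out <- out[order(out$barcode, out$call, out$indel_size), ]
  rownames(out) <- NULL
  out
}

#' Classify indels into repair pathways and compute the MMEJ:NHEJ balance
#'
#' Per barcode, indel reads (calls `del` and `ins`; wild-type and
#' recognition-named reads are excluded from every denominator, as are
#' `wt_point_mut` and `not_clear`) are routed by the rules: sizes in the
#' NHEJ signature list count as NHEJ; deletions matching an MMEJ signature
#' count as MMEJ — by size alone in count mode, or additionally requiring
#' the signature's microhomology length when per-size details from
#' [align_scar()] are supplied; everything else is `other`. The pathway
#' balance is `mmej_fraction = MMEJ / (MMEJ + NHEJ)`, absent when both are
#' zero. The fraction is invariant to scaling all counts by a constant.
#'
#' @param counts a `scar_count` data.frame (already QC-filtered).
#' @param rules a `pathway_rules`.
#' @param detail optional data.frame mapping observed deletions to
#'   microhomologies, with columns `barcode`, `indel_size`,
#'   `microhomology_len`, `reads`; when given, MMEJ signatures with a
#'   non-NA `mh_len` only absorb reads whose microhomology matches.
#' @return data.frame: `barcode`, `total_reads`, `total_indel_reads`,
#'   `mmej_count`, `nhej_count`, `other_count`, `mmej_fraction`.
#' @export
classify_pathways <- function(counts, rules = pathway_rules(), detail = NULL) {
  mmej_sizes <- c(rules$mmej_signatures$indel_size,
                  if (!is.null(detail)) rules$extra_mmej$indel_size)
  mmej_mh <- c(rules$mmej_signatures$mh_len,
               if (!is.null(detail)) rules$extra_mmej$mh_len)
  rows <- lapply(split(seq_len(nrow(counts)), counts$barcode), function(ix) {
    g <- counts[ix, , drop = FALSE]
    is_indel <- g$call %in% c("del", "ins")
    nhej <- sum(g$reads[is_indel & g$indel_size %in% rules$nhej_signatures])
    mmej <- 0L
    for (j in seq_along(mmej_sizes)) {
      sz <- mmej_sizes[j]
      cand <- sum(g$reads[is_indel & g$indel_size == sz])
      if (cand == 0L) next
      if (!is.null(detail) && !is.na(mmej_mh[j])) {
        dd <- detail[detail$barcode == g$barcode[1] &
                     detail$indel_size == sz, , drop = FALSE]
        cand <- sum(dd$reads[dd$microhomology_len == mmej_mh[j]])
      }
      mmej <- mmej + cand
    }
    total_indel <- sum(g$reads[is_indel])
    other <- total_indel - mmej - nhej
    data.frame(barcode = g$barcode[1],
               total_reads = sum(g$reads),
               total_indel_reads = total_indel,
               mmej_count = mmej, nhej_count = nhej, other_count = other,
               mmej_fraction = if (mmej + nhej > 0) mmej / (mmej + nhej)
                               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discover NHEJ indel types from inhibitor data
#'
#' Indel types whose ratio is at least `params$dmso_min_ratio` in the
#' vehicle (DMSO) condition are tested for a decrease under DNA-PK
#' inhibition with a one-sided Wilcoxon rank-sum test across per-barcode
#' (or per-replicate) ratio values; p-values are Benjamini-Hochberg
#' adjusted across the tested types and a type is labelled NHEJ iff its
#' adjusted p-value is below `params$alpha_adj`. Types below the vehicle
#' ratio floor, or with fewer than `min_n` values in either condition, are
#' reported untested rather than guessed.
#'
#' @param dmso,inhibited data.frames with columns `indel_type` (any label,
#'   e.g. `"ins_1"`), `unit` (barcode or replicate id) and `ratio` (the
#'   indel type's proportion in that unit).
#' @param params a `pipeline_params`.
#' @param min_n minimum values per condition for a meaningful rank test
#'   (default 3).
#' @return data.frame: `indel_type`, `dmso_mean`, `n_dmso`, `n_inhibited`,
#'   `tested`, `p_value`, `p_adj`, `nhej`.
#' @export
classify_nhej_by_inhibitor <- function(dmso, inhibited,
                                       params = pipeline_params(),
                                       min_n = 3L) {
  types <- sort(unique(c(dmso$indel_type, inhibited$indel_type)))
  res <- do.call(rbind, lapply(types, function(tp) {
    x <- dmso$ratio[dmso$indel_type == tp]
    y <- inhibited$ratio[inhibited$indel_type == tp]
    dm <- if (length(x)) mean(x) else 0
    testable <- dm >= params$dmso_min_ratio &&
      length(x) >= min_n && length(y) >= min_n
    p <- NA_real_
    if (testable)
      p <- suppressWarnings(
        wilcox.test(y, x, alternative = "less")$p.value)
    data.frame(indel_type = tp, dmso_mean = dm,
               n_dmso = length(x), n_inhibited = length(y),
               tested = testable, p_value = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- NA_real_
  res$p_adj[res$tested] <- p.adjust(res$p_value[res$tested], method = "BH")
  res$nhej <- !is.na(res$p_adj) & res$p_adj < params$alpha_adj
  rownames(res) <- NULL
  res
}

#' Join pathway summaries with integration calls
#'
#' Inner join of pass-filtered integration sites with per-barcode pathway
#' summaries, linking each reporter's repair balance to its genomic
#' location. Barcodes present in only one of the two tables are counted in
#' the attributes `n_unmapped` (summary only) and `n_no_scars`
#' (integration only).
#'
#' @param summary output of [classify_pathways()].
#' @param calls output of [filter_locations()].
#' @return joined data.frame (pass integrations only) with both tables'
#'   columns.
#' @export
summarize_pool <- function(summary, calls) {
  passed <- calls[calls$status == "pass", , drop = FALSE]
  joined <- merge(passed[, c("barcode", "chrom", "pos", "strand")], summary,
                  by = "barcode")
  joined <- joined[order(joined$barcode), ]
  rownames(joined) <- NULL
  attr(joined, "n_unmapped") <- sum(!summary$barcode %in% passed$barcode)
  attr(joined, "n_no_scars") <- sum(!passed$barcode %in% summary$barcode)
  joined
}
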