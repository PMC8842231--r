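## Barcode error correction: greedy sphere clustering under Levenshtein
## distance, with the genuine barcode defined as the most abundant member.

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' computed by `utils::adist`.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Cluster barcodes into genuine/mutated groups
#'
#' Greedy sphere clustering: candidate centres are processed in order of
#' decreasing count (ties broken lexicographically so runs are
#' deterministic); every still-unassigned barcode within Levenshtein
#' distance `max_dist` of the current centre joins its cluster, and the
#' centre becomes the cluster's genuine barcode. The protocol's criterion
#' "Levenshtein distance < 2" corresponds to the default `max_dist = 1`.
#' Barcodes of 15 or 17 bp cluster with 16-mers naturally, since the edit
#' distance absorbs length differences.
#'
#' @param counts named integer vector: barcode -> observed count (all >= 1).
#' @param max_dist clustering radius (default 1).
#' @return data.frame of class `cluster_table` with columns
#'   `member_barcode`, `genuine_barcode`, `count` (member count) and
#'   `cluster_total` (sum of member counts, identical on every row of one
#'   cluster).
#' @export
cluster_barcodes <- function(counts, max_dist = 1L) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (any(counts < 1L)) stop("all counts must be >= 1")
  bcs <- names(counts)
  if (is.null(bcs) || any(!nzchar(bcs))) stop("counts must be named by barcode")
  ord <- order(-as.numeric(counts), bcs)
  bcs <- bcs[ord]; cnt <- as.integer(counts[ord])
  n <- length(bcs)
  assigned <- rep(NA_integer_, n)          # index of the centre
  lens <- nchar(bcs)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    assigned[i] <- i
    open <- which(is.na(assigned))
    if (!length(open)) next
    ## length pre-screen: |len(a)-len(b)| <= max_dist is necessary
    open <- open[abs(lens[open] - lens[i]) <= max_dist]
    if (!length(open)) next
    d <- as.integer(adist(bcs[i], bcs[open]))
    assigned[open[d <= max_dist]] <- i
  }
  totals <- tapply(cnt, assigned, sum)
  out <- data.frame(member_barcode = bcs,
                    genuine_barcode = bcs[assigned],
                    count = cnt,
                    cluster_total = as.integer(totals[as.character(assigned)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cluster_total, out$genuine_barcode,
                   -out$count, out$member_barcode), ]
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Apply a cluster table to barcode-keyed records
#'
#' In `filter` mode, rows whose barcode is not a genuine barcode are
#' dropped. In `rescue` mode, rows are rewritten to their cluster's genuine
#' barcode and, when `count_col` is given, rows that become identical on
#' every other column are merged by summing that column. Barcodes absent
#' from the table are dropped and counted in the `"n_unknown"` attribute,
#' never raised as an error.
#'
#' @param table a `cluster_table`.
#' @param records data.frame with a `barcode` column.
#' @param mode `"filter"` (default) or `"rescue"`.
#' @param count_col optional name of a count column to sum when merging
#'   rescued rows.
#' @return filtered/rewritten data.frame with attribute `n_unknown`.
#' @export
apply_clusters <- function(table, records, mode = c("filter", "rescue"),
                           count_col = NULL) {
  mode <- match.arg(mode)
  stopifnot("barcode" %in% names(records))
  if (mode == "filter") {
    keep <- records$barcode %in% unique(table$genuine_barcode)
    known <- records$barcode %in% table$member_barcode
    out <- records[keep, , drop = FALSE]
    attr(out, "n_unknown") <- sum(!known)
    rownames(out) <- NULL
    return(out)
  }
  map <- setNames(table$genuine_barcode, table$member_barcode)
  known <- records$barcode %in% names(map)
  out <- records[known, , drop = FALSE]
  out$barcode <- unname(map[out$barcode])
  if (!is.null(count_col) && count_col %in% names(out)) {
    keys <- setdiff(names(out), count_col)
    agg <- stats::aggregate(out[[count_col]], by = out[keys], FUN = sum)
    names(agg)[ncol(agg)] <- count_col
    out <- agg[, names(out), drop = FALSE]
  }
  attr(out, "n_unknown") <- sum(!known)
  rownames(out) <- NULL
  out
}

#' Write a cluster table as TSV
#'
#' Three columns: member barcode, genuine barcode, total occurrences of the
#' cluster.
#'
#' @param table a `cluster_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  write.table(table[, c("member_barcode", "genuine_barcode", "cluster_total")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
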