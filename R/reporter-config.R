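#' Reporter specification
#'
#' Describes one barcoded DSB-repair reporter as read by the indel PCR: the
#' wild-type amplicon downstream of the barcode cassette, the two constant
#' adapter arms that flank the 16 bp reporter barcode, the expected blunt
#' Cas9 cut position, the downstream marker spacers whose positional shift
#' measures indel size, and the named recognition sequences that label calls.
#'
#' All amplicon offsets (`cut_offset`, spacer `offset`) are 0-based positions
#' in `wt_amplicon`, whose position 0 is the first base after `adapter_3p`.
#'
#' @param wt_amplicon wild-type reporter sequence downstream of the barcode
#'   cassette (first base after `adapter_3p`).
#' @param adapter_5p constant sequence immediately 5' of the barcode.
#' @param adapter_3p constant sequence immediately 3' of the barcode.
#' @param barcode_len_expected designed barcode length in bp.
#' @param barcode_len_range tolerated barcode length interval, length-2 integer.
#' @param cut_offset 0-based position in `wt_amplicon` of the first base 3' of
#'   the expected blunt cut.
#' @param spacers data.frame with columns `seq` (6 bp marker sequences) and
#'   `offset` (0-based expected position in `wt_amplicon`), strictly increasing.
#' @param recognition_seqs named character vector of exact sequences whose
#'   presence names a read's call; must include `"wt"`, a substring of
#'   `wt_amplicon` spanning `cut_offset`.
#' @param ipcr_read2_constant constant transposon-edge pattern required on
#'   read 2 of inverse-PCR pairs ("" disables the check).
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return an object of class `reporter_spec` (a named list).
#' @seealso [validate_reporter_spec()], [load_config()], [make_reporter()]
#' @export
reporter_spec <- function(wt_amplicon,
                          adapter_5p = "GTCACAAGGGCCGGCCACAA",
                          adapter_3p = "TGATC",
                          barcode_len_expected = 16L,
                          barcode_len_range = c(15L, 17L),
                          cut_offset,
                          spacers,
                          recognition_seqs,
                          ipcr_read2_constant = "",
                          validate = TRUE) {
  spacers <- as.data.frame(spacers, stringsAsFactors = FALSE)
  spec <- structure(list(
    wt_amplicon = toupper(wt_amplicon),
    adapter_5p = toupper(adapter_5p),
    adapter_3p = toupper(adapter_3p),
    barcode_len_expected = as.integer(barcode_len_expected),
    barcode_len_range = as.integer(barcode_len_range),
    cut_offset = as.integer(cut_offset),
    spacers = data.frame(seq = toupper(spacers$seq),
                         offset = as.integer(spacers$offset),
                         stringsAsFactors = FALSE),
    recognition_seqs = toupper(unlist(recognition_seqs)),
    ipcr_read2_constant = toupper(ipcr_read2_constant)
  ), class = "reporter_spec")
  if (validate) {
    errs <- validate_reporter_spec(spec)
    if (length(errs))
      stop("invalid reporter_spec:\n  - ", paste(errs, collapse = "\n  - "))
  }
  spec
}

#' Validate a reporter specification
#'
#' Collects every invariant violation rather than stopping at the first:
#' non-empty DNA adapter arms; expected barcode length within the tolerated
#' range; every spacer occurring exactly once in the amplicon, at its stated
#' offset, with offsets strictly increasing; a mandatory `"wt"` recognition
#' sequence that is a substring of the amplicon spanning the cut position.
#'
#' @param spec a `reporter_spec`.
#' @return character vector of violation messages (length 0 when valid).
#' @export
validate_reporter_spec <- function(spec) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  wt <- spec$wt_amplicon
  if (!nzchar(spec$adapter_5p) || !is_dna(spec$adapter_5p))
    push("adapter_5p must be a non-empty DNA string")
  if (!nzchar(spec$adapter_3p) || !is_dna(spec$adapter_3p))
    push("adapter_3p must be a non-empty DNA string")
  if (!is_dna(wt)) push("wt_amplicon must be a non-empty DNA string")
  if (length(spec$barcode_len_range) != 2L ||
      spec$barcode_len_expected < spec$barcode_len_range[1] ||
      spec$barcode_len_expected > spec$barcode_len_range[2])
    push("barcode_len_expected must lie within barcode_len_range")
  if (is.na(spec$cut_offset) || spec$cut_offset < 0L ||
      spec$cut_offset >= nchar(wt))
    push("cut_offset must be a 0-based position inside wt_amplicon")
  sp <- spec$spacers
  if (nrow(sp) == 0L) {
    push("at least one spacer is required")
  } else {
    if (any(diff(sp$offset) <= 0))
      push("spacer offsets must be strictly increasing")
    for (i in seq_len(nrow(sp))) {
      n_occ <- length(gregexpr(sp$seq[i], wt, fixed = TRUE)[[1]])
      if (gregexpr(sp$seq[i], wt, fixed = TRUE)[[1]][1] == -1L) n_occ <- 0L
      if (n_occ != 1L)
        push(sprintf("spacer %d (%s) occurs %d times in wt_amplicon (must be exactly 1)",
                     i, sp$seq[i], n_occ))
      else if (substr(wt, sp$offset[i] + 1L, sp$offset[i] + nchar(sp$seq[i])) != sp$seq[i])
        push(sprintf("spacer %d (%s) is not at its expected offset %d",
                     i, sp$seq[i], sp$offset[i]))
    }
  }
  rs <- spec$recognition_seqs
  if (!("wt" %in% names(rs))) {
    push("recognition_seqs must include 'wt'")
  } else {
    hit <- regexpr(rs[["wt"]], wt, fixed = TRUE)
    if (hit == -1L) {
      push("recognition_seqs['wt'] must be a substring of wt_amplicon")
    } else {
      start0 <- as.integer(hit) - 1L
      if (!(start0 <= spec$cut_offset &&
            spec$cut_offset < start0 + nchar(rs[["wt"]])))
        push("recognition_seqs['wt'] must span cut_offset")
    }
  }
  errs
}

#' Pipeline parameters
#'
#' Holds every threshold used downstream, with the defaults of the protocol:
#' barcode clustering radius (Levenshtein distance strictly below 2, i.e.
#' `max_barcode_dist = 1`), integration-site filters (>= 5 inverse-PCR reads,
#' average MAPQ > 10, >= 95 % of reads at the primary location, <= 2.5 % at a
#' secondary one), pool-abundance assumptions (100,000 cells, 6 barcodes per
#' cell on average, keep barcodes seen in >= 50 estimated cells), adapter
#' mismatch tolerance, and inhibitor-classification thresholds (DMSO indel
#' ratio >= 0.01, BH-adjusted p < 0.05).
#'
#' @param max_barcode_dist Levenshtein clustering radius.
#' @param min_ipcr_reads minimum reads at the primary integration location.
#' @param min_avg_mapq minimum average mapping quality at the primary location
#'   (strict inequality).
#' @param min_primary_frac minimum fraction of a barcode's reads at the
#'   primary location.
#' @param max_secondary_frac maximum fraction of reads at a secondary location.
#' @param total_cells_assumed assumed number of cells per experiment.
#' @param mean_barcodes_per_cell assumed mean barcodes per cell.
#' @param min_cells minimum estimated cells for a barcode to be kept.
#' @param adapter_max_mismatches substitutions tolerated per adapter arm
#'   (arms of 5 bp or less always require an exact match).
#' @param dmso_min_ratio minimum vehicle-condition indel ratio for an indel
#'   type to be tested in inhibitor classification.
#' @param alpha_adj adjusted-p threshold for labelling an indel type NHEJ.
#' @return an object of class `pipeline_params` (a named list).
#' @export
pipeline_params <- function(max_barcode_dist = 1L,
                            min_ipcr_reads = 5L,
                            min_avg_mapq = 10,
                            min_primary_frac = 0.95,
                            max_secondary_frac = 0.025,
                            total_cells_assumed = 100000L,
                            mean_barcodes_per_cell = 6,
                            min_cells = 50,
                            adapter_max_mismatches = 1L,
                            dmso_min_ratio = 0.01,
                            alpha_adj = 0.05) {
  p <- structure(list(
    max_barcode_dist = as.integer(max_barcode_dist),
    min_ipcr_reads = as.integer(min_ipcr_reads),
    min_avg_mapq = as.numeric(min_avg_mapq),
    min_primary_frac = as.numeric(min_primary_frac),
    max_secondary_frac = as.numeric(max_secondary_frac),
    total_cells_assumed = as.integer(total_cells_assumed),
    mean_barcodes_per_cell = as.numeric(mean_barcodes_per_cell),
    min_cells = as.numeric(min_cells),
    adapter_max_mismatches = as.integer(adapter_max_mismatches),
    dmso_min_ratio = as.numeric(dmso_min_ratio),
    alpha_adj = as.numeric(alpha_adj)
  ), class = "pipeline_params")
  errs <- character(0)
  fr <- c("min_primary_frac", "max_secondary_frac", "dmso_min_ratio", "alpha_adj")
  for (f in fr)
    if (p[[f]] < 0 || p[[f]] > 1)
      errs <- c(errs, sprintf("%s must be in [0,1]", f))
  if (p$min_primary_frac + p$max_secondary_frac > 1)
    errs <- c(errs, "min_primary_frac + max_secondary_frac must be <= 1")
  cnt <- c("max_barcode_dist", "min_ipcr_reads", "total_cells_assumed",
           "adapter_max_mismatches")
  for (f in cnt)
    if (is.na(p[[f]]) || p[[f]] < 0)
      errs <- c(errs, sprintf("%s must be a count >= 0", f))
  if (length(errs))
    stop("invalid pipeline_params:\n  - ", paste(errs, collapse = "\n  - "))
  p
}

## keys recognised in the config file; anything else at the top level is
## assumed to belong to a workflow engine and ignored with a warning
.config_reporter_keys <- c("wt_amplicon", "adapter_5p", "adapter_3p",
                           "barcode_len_expected", "barcode_len_range",
                           "cut_offset", "spacers", "recognition_seqs",
                           "ipcr_read2_constant")
.config_param_keys <- names(formals(pipeline_params))

#' Read a pipeline configuration file
#'
#' The configuration is a flat YAML document with two blocks: `reporter`
#' (the reporter model, see [reporter_spec()]) and `params` (thresholds, see
#' [pipeline_params()]). Absent optional `params` keys take their documented
#' defaults. Unknown top-level keys (e.g. workflow-engine settings) are
#' ignored with a warning. Missing required reporter keys raise a
#' configuration error naming the key; invariant violations are reported all
#' at once.
#'
#' @param path path to the YAML configuration file.
#' @return list with elements `spec` (`reporter_spec`) and `params`
#'   (`pipeline_params`).
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  extra <- setdiff(names(y), c("reporter", "params"))
  if (length(extra))
    warning("ignoring unknown configuration keys: ", paste(extra, collapse = ", "))
  rep <- y$reporter
  if (is.null(rep)) stop("configuration error: missing 'reporter' block")
  required <- c("wt_amplicon", "cut_offset", "spacers", "recognition_seqs")
  miss <- setdiff(required, names(rep))
  if (length(miss))
    stop("configuration error: missing required key(s): ",
         paste(miss, collapse = ", "))
  unknown_rep <- setdiff(names(rep), .config_reporter_keys)
  if (length(unknown_rep))
    warning("ignoring unknown reporter keys: ", paste(unknown_rep, collapse = ", "))
  spacers <- do.call(rbind, lapply(rep$spacers, function(s)
    data.frame(seq = s$seq, offset = s$offset, stringsAsFactors = FALSE)))
  rs <- unlist(rep$recognition_seqs)
  args <- list(wt_amplicon = rep$wt_amplicon, cut_offset = rep$cut_offset,
               spacers = spacers, recognition_seqs = rs)
  for (k in c("adapter_5p", "adapter_3p", "barcode_len_expected",
              "barcode_len_range", "ipcr_read2_constant"))
    if (!is.null(rep[[k]])) args[[k]] <- rep[[k]]
  spec <- do.call(reporter_spec, args)
  pk <- as.list(y$params)[intersect(names(y$params), .config_param_keys)]
  unknown_par <- setdiff(names(y$params), .config_param_keys)
  if (length(unknown_par))
    warning("ignoring unknown parameter keys: ", paste(unknown_par, collapse = ", "))
  params <- do.call(pipeline_params, pk)
  list(spec = spec, params = params)
}

#' Write a pipeline configuration file
#'
#' Inverse of [load_config()]: `load_config(write_config(spec, params, path))`
#' reproduces both objects exactly.
#'
#' @param spec a `reporter_spec`.
#' @param params a `pipeline_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, params, path) {
  rep <- unclass(spec)
  rep$spacers <- lapply(seq_len(nrow(spec$spacers)), function(i)
    list(seq = spec$spacers$seq[i], offset = spec$spacers$offset[i]))
  rep$recognition_seqs <- as.list(spec$recognition_seqs)
  yaml::write_yaml(list(reporter = rep, params = unclass(params)), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-delimited with a header; required columns `sample_name`,
#' `file_location`, `pcr_type` (one of `iPCR` / `indelPCR`,
#' case-insensitive); optional `guide_info`, `internal_index`, `condition`,
#' `replicate`. Several indel-PCR samples may share one FASTQ as long as
#' their `internal_index` values differ; demultiplexing happens at
#' extraction. File paths are resolved relative to the sheet's directory.
#'
#' @param path path to the TSV sample sheet.
#' @param check_files verify that each `file_location` exists (default TRUE).
#' @return data.frame of class `sample_sheet`.
#' @export
load_sample_sheet <- function(path, check_files = TRUE) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_name", "file_location", "pcr_type")
  miss <- setdiff(required, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("guide_info", "internal_index", "condition"))
    if (is.null(sheet[[opt]])) sheet[[opt]] <- NA_character_
  if (is.null(sheet$replicate)) sheet$replicate <- 1L
  dup <- sheet$sample_name[duplicated(sheet$sample_name)]
  if (length(dup))
    stop("duplicate sample_name(s): ", paste(unique(dup), collapse = ", "))
  canon <- c(ipcr = "iPCR", indelpcr = "indelPCR")
  key <- tolower(sheet$pcr_type)
  bad <- which(!key %in% names(canon))
  if (length(bad))
    stop("unknown pcr_type in row(s) ", paste(bad, collapse = ", "), ": ",
         paste(unique(sheet$pcr_type[bad]), collapse = ", "))
  sheet$pcr_type <- unname(canon[key])
  sheet$file_location <- ifelse(
    grepl("^/", sheet$file_location), sheet$file_location,
    file.path(dirname(path), sheet$file_location))
  if (check_files) {
    absent <- !file.exists(sheet$file_location)
    if (any(absent))
      stop("file(s) not found: ",
           paste(sheet$file_location[absent], collapse = ", "))
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}
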