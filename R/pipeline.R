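## Sample-sheet-driven orchestration of all stages, with per-sample outputs
## under a fixed naming scheme (<sample>.1.table / .2.table / .count) and a
## run manifest recording inputs, outputs and checksums.

.stage_order <- c("simulate", "extract", "cluster", "map", "call", "quantify")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, driven by a sample
#' sheet whose `pcr_type` routes each sample: indel-PCR samples flow
#' through extract -> cluster -> call -> quantify, inverse-PCR samples
#' (SAM alignments) through map. When the `simulate` stage is requested, a
#' seeded synthetic experiment is generated under `outdir/sim` together
#' with its configuration and sample sheet, and the remaining stages run on
#' it. Outputs land under `outdir`, one file set per sample:
#' `<sample>.bc.tsv` + `<sample>.stats.tsv` (extraction),
#' `<sample>.cluster.tsv` (clustering), `<sample>.1.table` and
#' `<sample>.2.table` (mapping), `<sample>.count` (scar calls), and pooled
#' `cell_estimates.tsv` / `pool_summary.tsv` (quantification). A manifest
#' (`manifest.yaml`) with per-file MD5 checksums is written atomically at
#' run end; deterministic stages reproduce identical checksums on rerun.
#'
#' @param stages character subset of
#'   `c("simulate","extract","cluster","map","call","quantify")`.
#' @param config_path pipeline configuration file (see [load_config()]);
#'   may be omitted when `simulate` is among the stages.
#' @param samples_path sample sheet (see [load_sample_sheet()]); may be
#'   omitted when `simulate` is among the stages.
#' @param outdir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param mode barcode cluster application: `"filter"` drops mutated
#'   barcodes, `"rescue"` reassigns them to their genuine barcode.
#' @param scar_mode `"count"` (spacer sizing only) or `"align"` (adds
#'   pairwise-alignment scar details).
#' @param genome_fasta optional FASTA used to realign soft-clipped chimera
#'   fragments (defaults to the simulated mini-genome when present).
#' @param sim_config optional `simulation_config` for the simulate stage.
#' @return the run manifest (named list), invisibly.
#' @export
run_pipeline <- function(stages, config_path = NULL, samples_path = NULL,
                         outdir, seed = 1L,
                         mode = c("filter", "rescue"),
                         scar_mode = c("count", "align"),
                         genome_fasta = NULL, sim_config = NULL) {
  mode <- match.arg(mode)
  scar_mode <- match.arg(scar_mode)
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stage_order[.stage_order %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log <- function(...) message(sprintf(...))

  if ("simulate" %in% stages) {
    simdir <- file.path(outdir, "sim")
    dir.create(simdir, showWarnings = FALSE)
    cfg <- sim_config %||% simulation_config(seed = seed, n_integrations = 20L,
                                             depth_per_barcode = 200L,
                                             ipcr_depth = 20L)
    spec <- make_reporter(seed)
    indel <- simulate_indel_reads(spec, cfg)
    ipcr <- simulate_ipcr(spec, cfg, barcodes = indel$barcodes)
    config_path <- file.path(simdir, "config.yaml")
    write_config(spec, pipeline_params(), config_path)
    fq <- file.path(simdir, "indel_R1.fastq")
    write_fastq(indel$reads, fq)
    sam <- file.path(simdir, "ipcr.sam")
    write_sam(ipcr$sam, ipcr$genome, sam)
    genome_fasta <- file.path(simdir, "genome.fa")
    write_genome_fasta(ipcr$genome, genome_fasta)
    write.table(indel$truth, file.path(simdir, "truth_indel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ipcr$integrations, file.path(simdir, "truth_integrations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    samples_path <- file.path(simdir, "samples.tsv")
    sheet <- data.frame(
      sample_name = c(names(indel$index_table), "ipcr1"),
      file_location = c(rep(basename(fq), length(indel$index_table)),
                        basename(sam)),
      pcr_type = c(rep("indelPCR", length(indel$index_table)), "iPCR"),
      guide_info = "synthetic",
      internal_index = c(unname(indel$index_table), NA),
      condition = "none", replicate = 1L, stringsAsFactors = FALSE)
    write.table(sheet, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <- c(outputs, config_path, fq, sam, genome_fasta, samples_path)
    log("simulate: %d reporters, %d indel reads, %d read pairs",
        cfg$n_integrations, length(indel$reads), nrow(ipcr$integrations) * cfg$ipcr_depth)
  }

  if (is.null(config_path) || is.null(samples_path))
    stop("config_path and samples_path are required unless 'simulate' is run")
  cf <- load_config(config_path)
  spec <- cf$spec; params <- cf$params
  sheet <- load_sample_sheet(samples_path)
  indel_rows <- which(sheet$pcr_type == "indelPCR")
  ipcr_rows <- which(sheet$pcr_type == "iPCR")

  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing input ", path, "; run the '", stage, "' stage first")
    path
  }

  if ("extract" %in% stages) {
    for (fq in unique(sheet$file_location[indel_rows])) {
      rows <- sheet[indel_rows, ][sheet$file_location[indel_rows] == fq, ,
                                  drop = FALSE]
      reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
      names(reads) <- sub("\\s.*", "", names(reads))
      demux <- !all(is.na(rows$internal_index))
      if (demux) {
        itab <- setNames(rows$internal_index, rows$sample_name)
        dm <- demultiplex_index(reads, itab,
                                max_mismatch = params$adapter_max_mismatches)
      } else {
        dm <- data.frame(sample = rows$sample_name[1], read = reads,
                         stringsAsFactors = FALSE)
      }
      for (s in rows$sample_name) {
        sel <- which(!is.na(dm$sample) & dm$sample == s)
        ex <- extract_barcodes(setNames(dm$read[sel], names(reads)[sel]),
                               spec, params)
        trimmed <- trim_readthrough(ex$remainder, spec, params)
        ex$remainder <- as.character(trimmed)
        st <- extraction_stats(ex, n_unassigned = sum(is.na(dm$sample)),
                               n_trimmed = attr(trimmed, "n_trimmed"))
        f1 <- file.path(outdir, paste0(s, ".bc.tsv"))
        f2 <- file.path(outdir, paste0(s, ".stats.tsv"))
        write.table(ex, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(st, f2, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, f1, f2)
        log("extract[%s]: %d reads in, %d barcodes out, %d failed",
            s, length(sel), sum(ex$step != "failed"), st$failed)
      }
    }
  }

  if ("cluster" %in% stages) {
    for (s in sheet$sample_name[indel_rows]) {
      bcf <- need(file.path(outdir, paste0(s, ".bc.tsv")), "extract")
      ex <- read.delim(bcf, stringsAsFactors = FALSE)
      ok <- ex[ex$step != "failed", , drop = FALSE]
      if (!nrow(ok)) next
      counts <- table(ok$barcode)
      tab <- cluster_barcodes(setNames(as.integer(counts), names(counts)),
                              max_dist = params$max_barcode_dist)
      f1 <- file.path(outdir, paste0(s, ".cluster.tsv"))
      write_cluster_table(tab, f1)
      applied <- apply_clusters(tab, ok, mode = mode)
      f2 <- file.path(outdir, paste0(s, ".bc_clustered.tsv"))
      write.table(applied, f2, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f1, f2)
      log("cluster[%s]: %d reads in, %d out (%s), %d clusters",
          s, nrow(ok), nrow(applied), mode,
          length(unique(tab$genuine_barcode)))
    }
  }

  if ("map" %in% stages) {
    genome <- NULL
    if (!is.null(genome_fasta) && file.exists(genome_fasta)) {
      g <- Biostrings::readDNAStringSet(genome_fasta)
      genome <- setNames(as.character(g), sub("\\s.*", "", names(g)))
    }
    for (i in ipcr_rows) {
      s <- sheet$sample_name[i]
      aln <- read_alignments(sheet$file_location[i])
      r2 <- triage_softclip(aln[aln$mate == "r2", , drop = FALSE])
      kept <- r2[r2$triage == "keep", , drop = FALSE]
      if (!is.null(genome)) {
        re <- realign_clipped(r2, genome)
        kept <- rbind(kept, re)
      }
      tab2 <- aggregate_locations(kept)
      calls <- filter_locations(tab2, params)
      f2 <- file.path(outdir, paste0(s, ".2.table"))
      write_mapping_table(tab2, calls, f2)
      r1 <- aln[aln$mate == "r1", , drop = FALSE]
      tab1 <- aggregate_locations(r1)
      f1 <- file.path(outdir, paste0(s, ".1.table"))
      write_mapping_table(tab1, filter_locations(tab1, params), f1)
      outputs <- c(outputs, f1, f2)
      log("map[%s]: %d alignments in, %d kept, %d/%d barcodes pass",
          s, nrow(aln), nrow(kept), sum(calls$status == "pass"), nrow(calls))
    }
  }

  if ("call" %in% stages) {
    for (s in sheet$sample_name[indel_rows]) {
      f <- file.path(outdir, paste0(s, ".bc_clustered.tsv"))
      if (!file.exists(f)) f <- need(file.path(outdir, paste0(s, ".bc.tsv")),
                                     "extract")
      ex <- read.delim(f, stringsAsFactors = FALSE)
      ex <- ex[!is.na(ex$barcode), , drop = FALSE]
      ex$remainder[is.na(ex$remainder)] <- ""
      cls <- classify_reads(ex$remainder, spec)
      counts <- count_scars(ex$barcode, cls)
      fo <- file.path(outdir, paste0(s, ".count"))
      write_scar_counts(counts, fo)
      outputs <- c(outputs, fo)
      if (scar_mode == "align") {
        det <- align_scar(ex$remainder, spec)
        det <- cbind(barcode = ex$barcode, det)
        fd <- file.path(outdir, paste0(s, ".detail.tsv"))
        write.table(det, fd, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, fd)
      }
      log("call[%s]: %d reads in, %d scar rows out", s, nrow(ex), nrow(counts))
    }
  }

  if ("quantify" %in% stages) {
    all_counts <- lapply(sheet$sample_name[indel_rows], function(s) {
      f <- need(file.path(outdir, paste0(s, ".count")), "call")
      x <- read.delim(f, stringsAsFactors = FALSE)
      class(x) <- c("scar_count", "data.frame")
      x
    })
    pooled <- do.call(rbind, all_counts)
    key <- paste(pooled$barcode, pooled$call, pooled$indel_size, sep = "\r")
    reads <- tapply(pooled$reads, key, sum)
    parts <- strsplit(names(reads), "\r", fixed = TRUE)
    pooled <- data.frame(
      barcode = vapply(parts, `[`, character(1), 1L),
      call = vapply(parts, `[`, character(1), 2L),
      indel_size = suppressWarnings(
        as.integer(vapply(parts, `[`, character(1), 3L))),
      reads = as.integer(reads), stringsAsFactors = FALSE)
    class(pooled) <- c("scar_count", "data.frame")
    filtered <- suppressMessages(filter_not_clear(pooled))
    cells <- estimate_cells(filtered, params)
    fc <- file.path(outdir, "cell_estimates.tsv")
    write.table(cells, fc, sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- classify_pathways(
      filtered[filtered$barcode %in% cells$barcode[cells$kept], , drop = FALSE])
    fs <- file.path(outdir, "pathway_summary.tsv")
    write.table(summary, fs, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, fc, fs)
    if (length(ipcr_rows)) {
      f2 <- need(file.path(outdir, paste0(sheet$sample_name[ipcr_rows[1]],
                                          ".2.table")), "map")
      mt <- read.delim(f2, stringsAsFactors = FALSE)
      calls <- data.frame(barcode = mt$barcode, chrom = mt$chrom,
                          pos = mt$start_1based, strand = mt$strand,
                          status = mt$status, reasons = mt$reasons,
                          stringsAsFactors = FALSE)
      pool <- summarize_pool(summary, calls)
      fp <- file.path(outdir, "pool_summary.tsv")
      write.table(pool, fp, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, fp)
      log("quantify: %d reporters in pooled summary", nrow(pool))
    }
  }

  manifest <- list(
    tool = "tripscar",
    version = as.character(utils::packageVersion("tripscar")),
    seed = as.integer(seed),
    stages = stages,
    config = config_path,
    samples = samples_path,
    outdir = outdir,
    mode = mode,
    scar_mode = scar_mode,
    checksums = as.list(tools::md5sum(unique(outputs))))
  mpath <- file.path(outdir, "manifest.yaml")
  tmp <- tempfile(tmpdir = outdir)
  yaml::write_yaml(manifest, tmp)
  file.rename(tmp, mpath)
  invisible(manifest)
}
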