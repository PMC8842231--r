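## Synthetic DSB-TRIP experiments: reporter, mini-genome, integrations,
## indel-PCR reads, inverse-PCR read pairs with alignments, and ground truth.

## evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Study conditions for a synthetic barcoded-reporter experiment. Defaults
#' mirror the assay this package analyses: 150 bp single-end indel-PCR reads
#' at a median depth of 2,000 reads per reporter, an editing outcome spectrum
#' dominated by the wild-type sequence, a -7 bp microhomology-mediated
#' deletion and a +1 bp end-joining insertion, Illumina-like substitution
#' errors around 0.1 % per base, and a few percent of inverse-PCR fragments
#' that are circular-ligation chimeras.
#'
#' @param seed integer seed; the same configuration reproduces identical
#'   output byte for byte.
#' @param n_integrations number of reporter integrations (barcodes).
#' @param genome_size total mini-genome size in bp (split over two
#'   chromosomes).
#' @param read_len read length in bp.
#' @param depth_per_barcode indel-PCR reads per reporter.
#' @param ipcr_depth inverse-PCR read pairs per reporter.
#' @param substitution_error_rate per-base substitution probability applied
#'   to simulated reads.
#' @param barcode_mutation_rate fraction of reads whose barcode carries one
#'   substitution (PCR/sequencing jackpot errors).
#' @param chimera_rate fraction of inverse-PCR fragments ligated to a distant
#'   locus, producing soft-clipped alignments.
#' @param indel_spectrum named probabilities over outcomes. Recognised names:
#'   `wt`, `mmej_del` (the engineered -7 deletion with 3 bp microhomology),
#'   `nhej_ins` (+1 insertion), `unclear` (a lesion destroying both the
#'   recognition window and all spacers), and generic `del<k>` / `ins<k>`.
#'   Must sum to 1.
#' @param mmej_fraction_range interval from which per-reporter programmed
#'   MMEJ fractions are drawn when spectra are generated per reporter.
#' @param drift optional list `list(days =, rate_sdlog =)` enabling clonal
#'   growth-rate drift simulation.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_integrations = 100L,
                              genome_size = 1e5,
                              read_len = 150L,
                              depth_per_barcode = 2000L,
                              ipcr_depth = 50L,
                              substitution_error_rate = 0.001,
                              barcode_mutation_rate = 0.01,
                              chimera_rate = 0.05,
                              indel_spectrum = c(wt = 0.5, mmej_del = 0.15,
                                                 nhej_ins = 0.35),
                              mmej_fraction_range = c(0.05, 0.95),
                              drift = NULL) {
  cfg <- structure(list(
    seed = as.integer(seed),
    n_integrations = as.integer(n_integrations),
    genome_size = as.integer(genome_size),
    read_len = as.integer(read_len),
    depth_per_barcode = as.integer(depth_per_barcode),
    ipcr_depth = as.integer(ipcr_depth),
    substitution_error_rate = substitution_error_rate,
    barcode_mutation_rate = barcode_mutation_rate,
    chimera_rate = chimera_rate,
    indel_spectrum = indel_spectrum,
    mmej_fraction_range = mmej_fraction_range,
    drift = drift
  ), class = "simulation_config")
  rates <- c(cfg$substitution_error_rate, cfg$barcode_mutation_rate,
             cfg$chimera_rate, cfg$indel_spectrum)
  if (any(rates < 0 | rates > 1))
    stop("all probabilities must lie in [0,1]")
  if (abs(sum(cfg$indel_spectrum) - 1) > 1e-8)
    stop("indel_spectrum must sum to 1")
  cfg
}

## fixed layout of the generated reporter (0-based amplicon offsets)
.rep_layout <- list(
  len = 150L,
  mh_start = 32L,          # first copy of the 3 bp direct repeat
  mh_len = 3L,
  gap_len = 4L,            # bases between the two repeat copies
  cut_offset = 37L,        # blunt cut between offsets 36 and 37
  recog_start = 28L, recog_len = 20L,
  spacer_start = 83L, spacer_len = 6L, n_spacers = 7L
)

#' Generate a random reporter specification
#'
#' Draws a random wild-type amplicon with the reporter's designed structure:
#' the constant barcode adapter arms, a blunt cut site flanked by an
#' engineered 3 bp direct repeat separated by 4 bp (so that the
#' microhomology-mediated deletion collapsing the repeat is exactly -7 bp
#' with a 3 bp microhomology), and seven unique 6 bp spacers occupying
#' amplicon offsets 83 through 124. The returned specification always passes
#' [validate_reporter_spec()]; the engineered deletion coordinates are
#' attached as attribute `"engineered"`.
#'
#' @param seed integer seed; equal seeds give identical specifications.
#' @return a `reporter_spec`.
#' @export
make_reporter <- function(seed = 1L) {
  L <- .rep_layout
  with_seed(seed, {
    repeat {
      amp <- sample(DNA_BASES, L$len, replace = TRUE)
      rep3 <- sample(DNA_BASES, L$mh_len, replace = TRUE)
      s1 <- L$mh_start + 1L                       # 1-based
      s2 <- s1 + L$mh_len + L$gap_len
      amp[s1:(s1 + L$mh_len - 1L)] <- rep3
      amp[s2:(s2 + L$mh_len - 1L)] <- rep3
      wt <- paste(amp, collapse = "")
      ## microhomology must be exactly 3 and the deletion unambiguous
      ok_mh <- substr(wt, L$mh_start, L$mh_start) !=
                 substr(wt, L$mh_start + 7L, L$mh_start + 7L) &&  # wt[31]!=wt[38] (0-based)
               substr(wt, L$mh_start + 4L, L$mh_start + 4L) !=
                 substr(wt, L$mh_start + 11L, L$mh_start + 11L)   # wt[35]!=wt[42]
      if (!ok_mh) next
      sp_off <- L$spacer_start + L$spacer_len * (seq_len(L$n_spacers) - 1L)
      spacers <- data.frame(
        seq = substr(rep(wt, L$n_spacers), sp_off + 1L, sp_off + L$spacer_len),
        offset = sp_off, stringsAsFactors = FALSE)
      recog <- substr(wt, L$recog_start + 1L, L$recog_start + L$recog_len)
      spec <- reporter_spec(
        wt_amplicon = wt,
        cut_offset = L$cut_offset,
        spacers = spacers,
        recognition_seqs = c(wt = recog),
        ipcr_read2_constant = paste(sample(DNA_BASES, 20L, replace = TRUE),
                                    collapse = ""),
        validate = FALSE)
      if (length(validate_reporter_spec(spec)) == 0L) {
        attr(spec, "engineered") <- list(
          mmej_del_start = L$mh_start, mmej_del_width = 7L,
          mh_len = L$mh_len)
        return(spec)
      }
    }
  })
}

## Apply one editing outcome to the wild-type amplicon. Returns the mutated
## amplicon string. Generic outcomes: "del<k>" removes k bp ending at the
## cut; "ins<k>" inserts k random bases at the cut.
mutate_amplicon <- function(spec, outcome) {
  wt <- spec$wt_amplicon
  cut <- spec$cut_offset                  # 0-based first base 3' of cut
  eng <- attr(spec, "engineered")
  switch_del <- function(start0, width) { # 0-based start, bp removed
    paste0(substr(wt, 1L, start0), substr(wt, start0 + width + 1L, nchar(wt)))
  }
  if (outcome == "wt") return(wt)
  if (outcome == "mmej_del") {
    if (is.null(eng)) stop("spec lacks engineered microhomology coordinates")
    return(switch_del(eng$mmej_del_start, eng$mmej_del_width))
  }
  if (outcome == "nhej_ins") {
    left <- substr(wt, 1L, cut)
    return(paste0(left, substr(left, cut, cut), substr(wt, cut + 1L, nchar(wt))))
  }
  if (outcome == "unclear") {
    ## lesion removing the recognition window and every spacer
    return(switch_del(20L, nchar(wt) - 25L))
  }
  m <- regmatches(outcome, regexec("^(del|ins)([0-9]+)$", outcome))[[1]]
  if (length(m) == 3L) {
    k <- as.integer(m[3])
    if (m[2] == "del") return(switch_del(cut - k + 1L, k))
    ins <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    return(paste0(substr(wt, 1L, cut), ins, substr(wt, cut + 1L, nchar(wt))))
  }
  stop("unknown outcome: ", outcome)
}

## expected call/size/microhomology for each outcome (truth bookkeeping)
outcome_truth <- function(spec, outcome) {
  eng <- attr(spec, "engineered")
  if (outcome == "wt")
    return(list(call = "wt", size = 0L, mh = 0L))
  if (outcome == "mmej_del")
    return(list(call = "del", size = -eng$mmej_del_width, mh = eng$mh_len))
  if (outcome == "nhej_ins")
    return(list(call = "ins", size = 1L, mh = 0L))
  if (outcome == "unclear")
    return(list(call = "not_clear", size = NA_integer_, mh = NA_integer_))
  m <- regmatches(outcome, regexec("^(del|ins)([0-9]+)$", outcome))[[1]]
  k <- as.integer(m[3])
  list(call = m[2], size = if (m[2] == "del") -k else k, mh = NA_integer_)
}

## inject substitution errors at `rate` per base; vectorised over reads
inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

## one random substitution in each of `bcs`
mutate_barcodes <- function(bcs) {
  vapply(bcs, function(b) {
    pos <- sample.int(nchar(b), 1L)
    ch <- strsplit(b, "")[[1]]
    ch[pos] <- sample(setdiff(DNA_BASES, ch[pos]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate indel-PCR reads
#'
#' Emits single-end reads with the full designed structure — internal sample
#' index, 5' adapter arm, reporter barcode, 3' adapter arm, edited amplicon,
#' then plasmid-backbone read-through (the reverse complement of the 5'
#' adapter) — truncated to the configured read length, together with a truth
#' table for every read. Barcode substitutions and sequencing errors are
#' injected at the configured rates.
#'
#' @param spec a `reporter_spec` from [make_reporter()] (or equivalent).
#' @param config a `simulation_config`.
#' @param barcodes optional character vector of reporter barcodes; defaults
#'   to `n_integrations` random unique 16-mers.
#' @param spectra optional list of per-barcode outcome spectra (each a named
#'   probability vector as in `simulation_config`); defaults to the shared
#'   `config$indel_spectrum`.
#' @param index_table named character vector, sample name -> internal index
#'   sequence; defaults to one sample `"sample1"` with a random 10-mer index.
#' @return list with `reads` (named character vector, names are read ids),
#'   `truth` (data.frame: read_id, sample, barcode, barcode_obs, outcome,
#'   true_call, true_indel_size, true_mh), `index_table` and `barcodes`.
#' @export
simulate_indel_reads <- function(spec, config, barcodes = NULL,
                                 spectra = NULL, index_table = NULL) {
  with_seed(config$seed + 1L, {
    if (is.null(barcodes)) {
      repeat {
        barcodes <- rand_dna(config$n_integrations, 16L)
        if (!anyDuplicated(barcodes)) break
      }
    }
    nb <- length(barcodes)
    if (is.null(index_table))
      index_table <- c(sample1 = paste(sample(DNA_BASES, 10L, replace = TRUE),
                                       collapse = ""))
    if (is.null(spectra)) spectra <- rep(list(config$indel_spectrum), nb)
    stopifnot(length(spectra) == nb)
    depth <- config$depth_per_barcode
    samples <- rep(names(index_table), length.out = nb)

    all_outcomes <- unique(unlist(lapply(spectra, names)))
    products <- setNames(vapply(all_outcomes, function(o)
      mutate_amplicon(spec, o), character(1)), all_outcomes)
    truths <- lapply(setNames(all_outcomes, all_outcomes),
                     function(o) outcome_truth(spec, o))

    bc_col <- rep(barcodes, each = depth)
    sample_col <- rep(samples, each = depth)
    outcome_col <- unlist(lapply(spectra, function(sp)
      sample(names(sp), depth, replace = TRUE, prob = sp)))
    n <- length(bc_col)
    read_id <- sprintf("indel_%07d", seq_len(n))

    bc_obs <- bc_col
    mut <- runif(n) < config$barcode_mutation_rate
    if (any(mut)) bc_obs[mut] <- mutate_barcodes(bc_col[mut])

    filler <- paste(sample(DNA_BASES, config$read_len, replace = TRUE),
                    collapse = "")
    reads <- paste0(index_table[sample_col], spec$adapter_5p, bc_obs,
                    spec$adapter_3p, products[outcome_col],
                    revcomp(spec$adapter_5p), filler)
    reads <- substr(reads, 1L, config$read_len)
    reads <- inject_errors(reads, config$substitution_error_rate)
    names(reads) <- read_id

    truth <- data.frame(
      read_id = read_id,
      sample = sample_col,
      barcode = bc_col,
      barcode_obs = bc_obs,
      outcome = outcome_col,
      true_call = vapply(outcome_col, function(o) truths[[o]]$call, character(1),
                         USE.NAMES = FALSE),
      true_indel_size = vapply(outcome_col, function(o) truths[[o]]$size,
                               integer(1), USE.NAMES = FALSE),
      true_mh = vapply(outcome_col, function(o) truths[[o]]$mh, integer(1),
                       USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, index_table = index_table,
         barcodes = barcodes)
  })
}

#' Draw per-reporter outcome spectra with programmed MMEJ fractions
#'
#' For parameter-recovery studies: each reporter keeps a fixed total editing
#' rate but its edited reads are split between the -7 microhomology deletion
#' and the +1 insertion according to a programmed MMEJ fraction drawn
#' uniformly from `config$mmej_fraction_range`.
#'
#' @param config a `simulation_config`.
#' @param n number of reporters.
#' @param edit_rate fraction of reads that are edited (non wild-type).
#' @return list with `spectra` (list of named probability vectors) and
#'   `mmej_fraction` (numeric vector of programmed fractions).
#' @export
draw_mmej_spectra <- function(config, n, edit_rate = 0.7) {
  with_seed(config$seed + 7L, {
    f <- runif(n, config$mmej_fraction_range[1], config$mmej_fraction_range[2])
    spectra <- lapply(f, function(p)
      c(wt = 1 - edit_rate, mmej_del = edit_rate * p,
        nhej_ins = edit_rate * (1 - p)))
    list(spectra = spectra, mmej_fraction = f)
  })
}

#' Simulate an inverse-PCR experiment
#'
#' Builds a random two-chromosome mini-genome, places one integration per
#' barcode, and emits read pairs: read 1 carries the barcode cassette
#' followed by the genomic fragment up to the nearest upstream GATC
#' (DpnII) site; read 2 carries the transposon-edge constant followed by the
#' genomic flank at the integration junction. A configurable fraction of
#' fragments are circular-ligation chimeras whose read-2 genomic portion
#' starts with a short piece of the true flank ligated to a distant locus;
#' their emitted alignments sit at the distant locus with a leading
#' soft-clip containing the true-junction piece. Alignments are emitted
#' directly as SAM (coordinates consistent with the mini-genome), so no
#' external aligner is needed.
#'
#' @param spec a `reporter_spec`.
#' @param config a `simulation_config`.
#' @param barcodes optional barcode vector (defaults to random unique
#'   16-mers).
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `integrations` (data.frame: barcode, chrom, pos, strand;
#'   `pos` is the 1-based junction base), `r1`, `r2` (named character read
#'   vectors), `sam` (data.frame of SAM fields for both mates), and
#'   `truth_reads` (per read-2: chimeric flag, clip length, distant locus).
#' @export
simulate_ipcr <- function(spec, config, barcodes = NULL) {
  with_seed(config$seed + 2L, {
    if (is.null(barcodes)) {
      repeat {
        barcodes <- rand_dna(config$n_integrations, 16L)
        if (!anyDuplicated(barcodes)) break
      }
    }
    nb <- length(barcodes)
    half <- as.integer(config$genome_size / 2L)
    genome <- c(chr1 = paste(sample(DNA_BASES, half, replace = TRUE), collapse = ""),
                chr2 = paste(sample(DNA_BASES, half, replace = TRUE), collapse = ""))
    margin <- 1000L
    integrations <- data.frame(
      barcode = barcodes,
      chrom = sample(names(genome), nb, replace = TRUE),
      pos = sample.int(half - 2L * margin, nb) + margin,
      strand = sample(c("+", "-"), nb, replace = TRUE),
      stringsAsFactors = FALSE)

    const <- spec$ipcr_read2_constant
    glen <- config$read_len - nchar(const)
    depth <- config$ipcr_depth
    n <- nb * depth
    bc <- rep(barcodes, each = depth)
    ichr <- rep(integrations$chrom, each = depth)
    ipos <- rep(integrations$pos, each = depth)
    istr <- rep(integrations$strand, each = depth)
    read_id <- sprintf("ipcr_%07d", seq_len(n))

    ## true genomic flank read from the junction, in read orientation
    flank <- ifelse(istr == "+",
      substr(genome[ichr], ipos, ipos + glen - 1L),
      revcomp(substr(genome[ichr], ipos - glen + 1L, ipos)))

    chim <- runif(n) < config$chimera_rate
    clip_len <- ifelse(chim, sample(5:30, n, replace = TRUE), 0L)
    dchr <- sample(names(genome), n, replace = TRUE)
    dstr <- sample(c("+", "-"), n, replace = TRUE)
    dpos <- sample.int(half - 2L * margin, n) + margin
    dlen <- glen - clip_len
    distant_piece <- ifelse(dstr == "+",
      substr(genome[dchr], dpos, dpos + dlen - 1L),
      revcomp(substr(genome[dchr], dpos - dlen + 1L, dpos)))
    genomic2 <- ifelse(chim,
      paste0(substr(flank, 1L, clip_len), distant_piece), flank)
    r2 <- setNames(paste0(const, genomic2), read_id)

    ## SAM records for read 2 (the transposon-edge mate), post constant-trim.
    ## Chimeric reads align at the distant locus with the true-junction piece
    ## soft-clipped at the read 5' end (CIGAR side depends on strand).
    sam2 <- data.frame(
      qname = read_id, mate = "r2", barcode = bc,
      flag = NA_integer_, rname = NA_character_, pos = NA_integer_,
      mapq = 42L, cigar = NA_character_, seq = genomic2,
      stringsAsFactors = FALSE)
    aln_str <- ifelse(chim, dstr, istr)
    sam2$flag <- 129L + ifelse(aln_str == "-", 16L, 0L)
    sam2$rname <- ifelse(chim, dchr, ichr)
    sam2$pos <- ifelse(chim,
      ifelse(dstr == "+", dpos, dpos - dlen + 1L),
      ifelse(istr == "+", ipos, ipos - glen + 1L))
    sam2$cigar <- ifelse(!chim, paste0(glen, "M"),
      ifelse(dstr == "+", paste0(clip_len, "S", dlen, "M"),
                          paste0(dlen, "M", clip_len, "S")))
    ## stored SEQ is reference-forward; reverse-strand reads are flipped
    sam2$seq <- ifelse(aln_str == "-", revcomp(genomic2), genomic2)

    ## read 1: barcode cassette + DpnII junction + fragment toward the
    ## nearest upstream GATC site (QC mate)
    cass_len <- nchar(spec$adapter_5p) + 16L + nchar(spec$adapter_3p)
    cap1 <- config$read_len - cass_len
    up <- find_upstream_gatc(genome, integrations)
    upos <- rep(up$gatc_pos, each = depth)       # 1-based GATC start, NA if none
    ## plus strand: fragment runs forward from the GATC start toward the
    ## junction; minus strand: it runs (in read orientation) from the end of
    ## the GATC back toward the junction, i.e. reference-reverse.
    gend <- upos + 3L
    avail <- ifelse(istr == "+",
                    ifelse(is.na(upos), cap1, ipos - upos),
                    ifelse(is.na(upos), cap1, gend - ipos))
    len1 <- pmin(cap1, avail)
    aln_start1 <- ifelse(istr == "+",
                         ifelse(is.na(upos), pmax(1L, ipos - cap1), upos),
                         ifelse(is.na(upos), ipos + cap1, gend) - len1 + 1L)
    len1 <- pmax(len1, 0L)
    ref1 <- substr(genome[ichr], aln_start1, aln_start1 + len1 - 1L)
    frag1 <- ifelse(istr == "+", ref1, revcomp(ref1))
    r1 <- setNames(paste0(spec$adapter_5p, bc, spec$adapter_3p, frag1), read_id)
    sam1 <- data.frame(
      qname = read_id, mate = "r1", barcode = bc,
      flag = 65L + ifelse(istr == "-", 16L, 0L),
      rname = ichr,
      pos = aln_start1,
      mapq = 42L,
      cigar = paste0(len1, "M"),
      seq = ref1,
      stringsAsFactors = FALSE)
    keep1 <- len1 > 0L
    sam <- rbind(sam1[keep1, ], sam2)

    truth_reads <- data.frame(
      read_id = read_id, barcode = bc, chimeric = chim,
      clip_len = clip_len,
      distant_chrom = ifelse(chim, dchr, NA_character_),
      distant_pos = ifelse(chim, ifelse(dstr == "+", dpos, dpos), NA_integer_),
      distant_strand = ifelse(chim, dstr, NA_character_),
      stringsAsFactors = FALSE)
    r1 <- inject_errors(r1, config$substitution_error_rate)
    list(genome = genome, integrations = integrations, r1 = r1, r2 = r2,
         sam = sam, truth_reads = truth_reads, barcodes = barcodes)
  })
}

## nearest GATC start strictly upstream of each integration (on the
## transposon-distal side); returns data.frame(gatc_pos)
find_upstream_gatc <- function(genome, integrations) {
  hits <- lapply(genome, function(s)
    as.integer(gregexpr("GATC", s, fixed = TRUE)[[1]]))
  gatc_pos <- vapply(seq_len(nrow(integrations)), function(i) {
    h <- hits[[integrations$chrom[i]]]
    if (length(h) == 1L && h[1] == -1L) return(NA_integer_)
    if (integrations$strand[i] == "+") {
      cand <- h[h + 3L < integrations$pos[i]]
      if (length(cand)) max(cand) else NA_integer_
    } else {
      cand <- h[h > integrations$pos[i]]
      if (length(cand)) min(cand) else NA_integer_
    }
  }, integer(1))
  data.frame(gatc_pos = gatc_pos)
}

#' Simulate clonal drift of barcode proportions
#'
#' Each clone grows exponentially with a log-normally distributed growth
#' rate; read proportions are renormalized per sampling day. Fast-cycling
#' clones progressively take over the pool.
#'
#' @param config a `simulation_config` with a non-NULL `drift` element
#'   (`list(days =, rate_sdlog =)`).
#' @param barcodes optional barcode names (defaults to `bc0001`...).
#' @return data.frame with columns `day`, `barcode`, `proportion`.
#' @export
simulate_drift <- function(config, barcodes = NULL) {
  if (is.null(config$drift)) stop("config$drift is not enabled")
  with_seed(config$seed + 3L, {
    n <- config$n_integrations
    if (is.null(barcodes)) barcodes <- sprintf("bc%04d", seq_len(n))
    rates <- rlnorm(n, meanlog = 0, sdlog = config$drift$rate_sdlog)
    days <- config$drift$days
    out <- do.call(rbind, lapply(days, function(d) {
      w <- exp(rates * d)
      data.frame(day = d, barcode = barcodes, proportion = w / sum(w),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Exact-match alignment against a mini-genome
#'
#' A deliberately naive aligner for the simulator's mini-genome: reports a
#' hit only when the query occurs exactly once across both strands of the
#' genome. Used to realign soft-clipped chimera fragments and for optional
#' FASTQ-to-SAM integration tests; not a general-purpose aligner.
#'
#' @param queries character vector of DNA sequences.
#' @param genome named character vector of chromosome sequences.
#' @param mapq mapping quality assigned to unique hits.
#' @return data.frame with one row per query: `chrom`, `pos` (1-based
#'   leftmost), `strand`, `mapq`, `ref_len`; NA row when the query is absent
#'   or ambiguous.
#' @export
naive_align <- function(queries, genome, mapq = 42L) {
  gset <- Biostrings::DNAStringSet(genome)
  out <- data.frame(chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, mapq = NA_integer_,
                    ref_len = nchar(queries), stringsAsFactors = FALSE)
  out <- out[rep(1L, length(queries)), , drop = FALSE]
  out$ref_len <- nchar(queries)
  rownames(out) <- NULL
  for (i in seq_along(queries)) {
    q <- queries[i]
    hits <- list()
    for (str in c("+", "-")) {
      pat <- if (str == "+") q else revcomp(q)
      m <- Biostrings::vmatchPattern(pat, gset)
      st <- Biostrings::startIndex(m)
      for (ci in seq_along(st))
        if (length(st[[ci]]))
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = names(genome)[ci], pos = st[[ci]], strand = str,
            stringsAsFactors = FALSE)
    }
    hits <- if (length(hits)) do.call(rbind, hits) else NULL
    if (!is.null(hits) && nrow(hits) == 1L) {
      out$chrom[i] <- hits$chrom
      out$pos[i] <- hits$pos
      out$strand[i] <- hits$strand
      out$mapq[i] <- mapq
    }
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads named character vector of reads.
#' @param path output path (plain text; use a `.gz` extension to compress).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write simulator alignments as SAM
#'
#' @param sam data.frame as produced by [simulate_ipcr()] (`$sam`).
#' @param genome named character vector of chromosome sequences (for the
#'   header's sequence dictionary).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tBC:Z:%s",
                     sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                     sam$cigar, sam$seq, strrep("I", nchar(sam$seq)),
                     sam$barcode), con)
  invisible(path)
}

#' Write a mini-genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
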