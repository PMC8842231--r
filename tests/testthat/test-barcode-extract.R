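spec <- test_spec
a5 <- spec$adapter_5p
a3 <- spec$adapter_3p

## a fixed barcode that cannot collide with the 3' arm by chance
bc16 <- "AAGGCCAAGGCCAAGG"

test_that("intact reads are extracted via the full step with exact barcodes", {
  read <- paste0(a5, bc16, a3, substr(spec$wt_amplicon, 1L, 80L))
  res <- extract_barcode(read, spec)
  expect_equal(res$step, "full")
  expect_equal(res$barcode, bc16)
  expect_equal(res$remainder, substr(spec$wt_amplicon, 1L, 80L))

  for (L in c(15L, 17L)) {
    bc <- substr(strrep("AAGGCC", 3L), 1L, L)
    res <- extract_barcode(paste0(a5, bc, a3, substr(spec$wt_amplicon, 1, 60)),
                           spec)
    expect_equal(res$step, "full")
    expect_equal(nchar(res$barcode), L)
    expect_equal(res$barcode, bc)
  }
})

test_that("a 5' arm broken by two substitutions falls back to the 3' step", {
  a5_bad <- a5
  substr(a5_bad, 3L, 3L) <- "T"   # G -> T
  substr(a5_bad, 12L, 12L) <- "A" # C -> A
  read <- paste0(a5_bad, bc16, a3, substr(spec$wt_amplicon, 1L, 80L))
  ## exhaustive mismatch-placement oracle: no window of the read matches the
  ## 5' arm within 1 substitution
  wins <- substring(read, 1:(nchar(read) - nchar(a5) + 1L),
                    nchar(a5):nchar(read))
  min_mm <- min(vapply(wins, function(w)
    sum(strsplit(w, "")[[1]] != strsplit(a5, "")[[1]]), integer(1)))
  expect_gte(min_mm, 2L)
  ## and the leftmost exact 3' arm occurrence is the designed one
  expect_equal(regexpr(a3, read, fixed = TRUE)[1], nchar(a5) + 17L)

  res <- extract_barcode(read, spec)
  expect_equal(res$step, "three_prime")
  expect_equal(res$barcode, bc16)
})

test_that("a broken 3' arm still yields the barcode from the 5' arm", {
  read <- paste0(a5, bc16, "GGGGG", substr(spec$wt_amplicon, 1L, 80L))
  res <- extract_barcode(read, spec)
  expect_equal(res$step, "five_prime")
  expect_equal(res$barcode, bc16)
})

test_that("extraction is position-independent and never errors on junk", {
  withr::local_seed(11)
  for (i in 1:20) {
    prefix <- paste(sample(c("A", "C", "G", "T"), sample(0:30, 1),
                           replace = TRUE), collapse = "")
    base <- paste0(a5, bc16, a3, substr(spec$wt_amplicon, 1L, 60L))
    expect_equal(extract_barcode(paste0(prefix, base), spec)$barcode, bc16)
  }
  short <- extract_barcode("ACGT", spec)
  expect_equal(short$step, "failed")
  expect_true(is.na(short$barcode))
})

test_that("internal indices demultiplex with Hamming tolerance", {
  itab <- c(s1 = "ACGTACGTAC", s2 = "TTGGCCAATT")
  r_exact <- paste0("ACGTACGTAC", a5, bc16, a3)
  r_onemm <- paste0("ACGTACGTAA", a5, bc16, a3)
  r_none <- paste0("GGGGGGGGGG", a5, bc16, a3)
  dm <- demultiplex_index(c(r_exact, r_onemm, r_none), itab, max_mismatch = 1)
  expect_equal(dm$sample, c("s1", "s1", NA))
  expect_equal(dm$read[1], paste0(a5, bc16, a3))   # index stripped
  expect_equal(dm$read[3], r_none)                  # untouched
  ## oracle: the one-mismatch read is distance 1 from s1 and >= 3 from s2
  pre <- substr(r_onemm, 1, 10)
  expect_equal(sum(strsplit(pre, "")[[1]] != strsplit(itab[1], "")[[1]]), 1L)
  expect_gte(sum(strsplit(pre, "")[[1]] != strsplit(itab[2], "")[[1]]), 3L)

  expect_error(demultiplex_index("ACGT", c(s1 = "ACGTACGTAC",
                                           s2 = "ACGTACGTAA")),
               "clashing")
})

test_that("backbone read-through is trimmed, with and without an error", {
  rem_clean <- substr(spec$wt_amplicon, 1L, 40L)
  expect_equal(as.character(trim_readthrough(rem_clean, spec)), rem_clean)

  rt <- revcomp(a5)
  rem_rt <- paste0(rem_clean, rt, "ACGTACGT")
  expect_equal(as.character(trim_readthrough(rem_rt, spec)), rem_clean)

  rt_err <- rt
  substr(rt_err, 5L, 5L) <- setdiff(c("A", "C", "G", "T"),
                                    substr(rt, 5L, 5L))[1]
  trimmed <- trim_readthrough(paste0(rem_clean, rt_err), spec)
  expect_equal(as.character(trimmed), rem_clean)
  expect_equal(attr(trimmed, "n_trimmed"), 1L)
})

test_that("extraction statistics conserve the read total", {
  cfg <- noiseless_config(seed = 5, n_integrations = 10,
                          depth_per_barcode = 30)
  sim <- simulate_indel_reads(test_spec, cfg)
  junk <- setNames(rep(strrep("ACGT", 40L), 7L), sprintf("junk_%d", 1:7))
  ex <- extract_barcodes(c(sim$reads, junk), spec)
  st <- extraction_stats(ex, n_unassigned = 3L, n_trimmed = 2L)
  expect_equal(st$total, st$full + st$five_prime + st$three_prime + st$failed)
  expect_equal(st$total, length(sim$reads) + 7L)
  expect_true(all(ex$step[ex$read_id %in% names(junk)] == "failed"))
  ## barcode present iff step != failed
  expect_equal(is.na(ex$barcode), ex$step == "failed")
})

test_that("inverse-PCR pairs require the read-2 constant and recover well under error", {
  cfg <- simulation_config(seed = 9, n_integrations = 50, ipcr_depth = 20,
                           substitution_error_rate = 0.001,
                           barcode_mutation_rate = 0, chimera_rate = 0)
  ip <- simulate_ipcr(spec, cfg)
  expect_true(all(startsWith(ip$r2, spec$ipcr_read2_constant)))
  pr <- extract_ipcr_pair(ip$r1, ip$r2, spec)
  expect_gte(mean(pr$pass), 0.99)           # 1,000 pairs at 0.1% error
  ok <- pr$pass
  truth_bc <- rep(ip$barcodes, each = cfg$ipcr_depth)
  ## errors can hit the barcode itself (~1.6% of reads at this rate); the
  ## recovered barcode is then one edit away and clustering absorbs it
  expect_gte(mean(pr$barcode[ok] == truth_bc[ok]), 0.97)
  expect_gte(mean(levenshtein(pr$barcode[ok], truth_bc[ok]) <= 1L), 0.999)
  ## genomic portion is read 2 beyond the constant
  expect_equal(pr$genomic[ok][1],
               unname(substr(ip$r2[ok][1],
                             nchar(spec$ipcr_read2_constant) + 1L,
                             nchar(ip$r2[ok][1]))))
  ## read 2 lacking the transposon constant rejects the pair
  bad <- extract_ipcr_pair(ip$r1[1], strrep("ACGT", 35L), spec)
  expect_false(bad$pass)
  expect_true(is.na(bad$genomic))
})
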