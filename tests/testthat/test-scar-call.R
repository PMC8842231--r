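spec <- test_spec
wt <- spec$wt_amplicon
eng <- attr(spec, "engineered")

test_that("recognition matching is exact, longest-first, and name-aware", {
  expect_equal(match_recognition(wt, spec), "wt")
  ## a 1 bp deletion inside the recognition window breaks the exact match
  mid <- spec$cut_offset            # 0-based, inside the window
  broken <- paste0(substr(wt, 1L, mid), substr(wt, mid + 2L, nchar(wt)))
  expect_true(is.na(match_recognition(broken, spec)))

  ## a designed insertion product gets its configured name even though the
  ## wild-type window is absent
  ins_prod <- tripscar:::mutate_amplicon(spec, "nhej_ins")
  spec2 <- spec
  spec2$recognition_seqs <- c(spec$recognition_seqs,
    ssODN = substr(ins_prod, spec$cut_offset - 8L, spec$cut_offset + 12L))
  expect_equal(match_recognition(ins_prod, spec2), "ssODN")
  expect_equal(match_recognition(wt, spec2), "wt")
})

test_that("spacer displacement sizes indels and survives downstream noise", {
  expect_identical(indel_size_by_spacers(wt, spec), 0L)
  del7 <- tripscar:::mutate_amplicon(spec, "mmej_del")
  expect_identical(indel_size_by_spacers(del7, spec), -7L)
  ins1 <- tripscar:::mutate_amplicon(spec, "nhej_ins")
  expect_identical(indel_size_by_spacers(ins1, spec), 1L)
  expect_true(is.na(indel_size_by_spacers("ACGTACGT", spec)))

  ## substitutions strictly downstream of the first intact spacer never
  ## change the size
  withr::local_seed(81)
  first_end <- spec$spacers$offset[1] + 6L   # 0-based end of spacer 1 in wt
  for (i in 1:25) {
    target <- sample(c("wt", "mmej_del"), 1)
    rem <- tripscar:::mutate_amplicon(spec, target)
    shift <- if (target == "wt") 0L else -7L
    p0 <- sample(seq(first_end + shift, nchar(rem) - 1L), 1)  # 0-based
    ch <- strsplit(rem, "")[[1]]
    ch[p0 + 1L] <- sample(setdiff(c("A", "C", "G", "T"), ch[p0 + 1L]), 1)
    expect_identical(indel_size_by_spacers(paste(ch, collapse = ""), spec),
                     shift)
  }
})

test_that("the call taxonomy is total and matches its defining cases", {
  expect_equal(classify_reads(wt, spec),
               data.frame(call = "wt", indel_size = 0L,
                          stringsAsFactors = FALSE))

  ## recognition intact but a 1 bp deletion past the window: wt with size -1
  recog_end0 <- regexpr(spec$recognition_seqs[["wt"]], wt, fixed = TRUE) +
    nchar(spec$recognition_seqs[["wt"]]) - 2L       # 0-based last base
  delpos <- recog_end0 + 5L
  odd <- paste0(substr(wt, 1L, delpos + 1L), substr(wt, delpos + 3L, nchar(wt)))
  got <- classify_reads(odd, spec)
  expect_equal(got$call, "wt")
  expect_equal(got$indel_size, -1L)

  ## both signals destroyed: not_clear with absent size
  wrecked <- substr(tripscar:::mutate_amplicon(spec, "unclear"), 1L, 25L)
  got2 <- classify_reads(wrecked, spec)
  expect_equal(got2$call, "not_clear")
  expect_true(is.na(got2$indel_size))

  ## no recognition, zero net size: wt_point_mut
  pm <- wt
  substr(pm, spec$cut_offset + 1L, spec$cut_offset + 1L) <-
    setdiff(c("A", "C", "G", "T"), substr(wt, spec$cut_offset + 1L,
                                          spec$cut_offset + 1L))[1]
  got3 <- classify_reads(pm, spec)
  expect_equal(got3$call, "wt_point_mut")
  expect_equal(got3$indel_size, 0L)

  ## totality + conservation over a simulated mixture
  cfg <- noiseless_config(seed = 91, n_integrations = 5,
                          depth_per_barcode = 100,
                          indel_spectrum = c(wt = 0.4, mmej_del = 0.2,
                                             nhej_ins = 0.2, unclear = 0.2))
  sim <- simulate_indel_reads(spec, cfg)
  dm <- demultiplex_index(sim$reads, sim$index_table)
  ex <- extract_barcodes(setNames(dm$read, names(sim$reads)), spec)
  rem <- as.character(trim_readthrough(ex$remainder, spec))
  cls <- classify_reads(rem, spec)
  expect_equal(cls$call, sim$truth$true_call)
  counts <- count_scars(sim$truth$barcode, cls)
  expect_equal(sum(counts$reads), length(sim$reads))
})

test_that("scar counting groups deterministically and handles empty input", {
  calls <- data.frame(call = c("wt", "wt", "wt", "del", "del"),
                      indel_size = c(0L, 0L, 0L, -7L, -7L),
                      stringsAsFactors = FALSE)
  cs <- count_scars(rep("bc1", 5), calls)
  expect_equal(cs$reads, c(2L, 3L))      # del sorts before wt
  expect_equal(cs$call, c("del", "wt"))

  empty <- count_scars(character(0),
                       data.frame(call = character(0),
                                  indel_size = integer(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("alignment mode resolves the engineered microhomology deletion exactly", {
  ## hand enumeration of the repeat collapse: the deleted interval
  ## [del_start, del_start+6] can slide across the 3 bp repeat, so the
  ## left-aligned deletion starts at the first repeat copy and the
  ## microhomology is the repeat length
  s0 <- eng$mmej_del_start                   # 0-based
  expect_equal(substr(wt, s0 + 1L, s0 + 3L),
               substr(wt, s0 + 8L, s0 + 10L))          # the direct repeat
  expect_false(substr(wt, s0 + 4L, s0 + 4L) ==
               substr(wt, s0 + 11L, s0 + 11L))         # ...of length exactly 3

  del7 <- tripscar:::mutate_amplicon(spec, "mmej_del")
  det <- align_scar(del7, spec)
  expect_true(det$aligned)
  expect_equal(det$net_size, -7L)
  expect_equal(det$del_start, s0)
  expect_equal(det$del_width, 7L)
  expect_equal(det$microhomology_len, eng$mh_len)

  clean <- align_scar(wt, spec)
  expect_equal(clean$net_size, 0L)
  expect_equal(clean$microhomology_len, 0L)

  ins <- align_scar(tripscar:::mutate_amplicon(spec, "nhej_ins"), spec)
  expect_equal(ins$net_size, 1L)

  garbage <- align_scar(strrep("AC", 50L), spec)
  expect_false(garbage$aligned)
})

test_that("spacer sizes equal alignment sizes on simulated single-indel reads", {
  withr::local_seed(101)
  outs <- c("wt", "mmej_del", "nhej_ins", paste0("del", c(2, 5, 12, 20)),
            paste0("ins", c(2, 4, 8)))
  rems <- vapply(sample(outs, 300, replace = TRUE), function(o)
    substr(tripscar:::mutate_amplicon(spec, o), 1L, 99L), character(1),
    USE.NAMES = FALSE)
  sp_size <- indel_size_by_spacers(rems, spec)
  al <- align_scar(rems, spec)
  expect_true(all(!is.na(sp_size)))
  expect_identical(sp_size, al$net_size)
})
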