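sc <- function(...) {
  x <- data.frame(...)
  class(x) <- c("scar_count", "data.frame")
  x
}

test_that("unresolvable calls are removed and their fraction reported", {
  tab <- sc(barcode = c("b1", "b1", "b1", "b2"),
            call = c("wt", "not_clear", "del", "not_clear"),
            indel_size = c(0L, NA, -7L, NA),
            reads = c(30L, 6L, 10L, 4L))
  out <- suppressMessages(filter_not_clear(tab))
  expect_false(any(out$call == "not_clear"))
  expect_equal(attr(out, "removed_frac"), 10 / 50)
  clean <- sc(barcode = "b1", call = "wt", indel_size = 0L, reads = 5L)
  out2 <- suppressMessages(filter_not_clear(clean))
  expect_equal(out2$reads, 5L)
  expect_equal(attr(out2, "removed_frac"), 0)

  ## simulated mixture with a known 20% unresolvable share
  cfg <- noiseless_config(seed = 15, n_integrations = 10,
                          depth_per_barcode = 500,
                          indel_spectrum = c(wt = 0.5, mmej_del = 0.15,
                                             nhej_ins = 0.15, unclear = 0.2))
  sim <- simulate_indel_reads(test_spec, cfg)
  dm <- demultiplex_index(sim$reads, sim$index_table)
  ex <- extract_barcodes(setNames(dm$read, names(sim$reads)), test_spec)
  rem <- as.character(trim_readthrough(ex$remainder, test_spec))
  counts <- count_scars(sim$truth$barcode, classify_reads(rem, test_spec))
  out3 <- suppressMessages(filter_not_clear(counts))
  expect_lt(abs(attr(out3, "removed_frac") - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("cell estimates follow the abundance formula and conserve the pool", {
  p <- pipeline_params()
  one <- sc(barcode = "b1", call = "wt", indel_size = 0L, reads = 1234L)
  est <- estimate_cells(one, p)
  expect_equal(est$estimated_cells, 600000)

  half <- sc(barcode = c("b1", "b2"), call = "wt", indel_size = 0L,
             reads = c(500L, 500L))
  expect_equal(estimate_cells(half, p)$estimated_cells, c(300000, 300000))

  ## a barcode at fraction 5e-5 of reads -> 30 estimated cells, dropped
  small <- sc(barcode = c("b1", "b2"), call = "wt", indel_size = 0L,
              reads = c(1L, 19999L))
  e <- estimate_cells(small, p)
  expect_equal(e$estimated_cells[e$barcode == "b1"], 30)
  expect_false(e$kept[e$barcode == "b1"])

  withr::local_seed(25)
  many <- sc(barcode = sprintf("b%03d", 1:40), call = "wt", indel_size = 0L,
             reads = sample(1:1000, 40))
  expect_equal(sum(estimate_cells(many, p)$estimated_cells), 600000)
  expect_error(estimate_cells(many[0, ], p), "at least one read")
})

test_that("replicate normalization removes depth differences exactly", {
  r1 <- sc(barcode = c("b1", "b1"), call = c("wt", "del"),
           indel_size = c(0L, -7L), reads = c(80L, 20L))
  single <- normalize_replicates(list(r1))
  expect_equal(single$proportion[single$call == "del"], 0.2)

  r2 <- r1; r2$reads <- r1$reads * 10L     # same fractions, 10x depth
  both <- normalize_replicates(list(r1, r2))
  expect_equal(both$proportion[both$call == "del"], 0.2)
  expect_equal(sum(both$proportion), 1)

  ## three replicates drawn from one multinomial stay near the truth
  withr::local_seed(35)
  probs <- c(wt = 0.6, del = 0.3, ins = 0.1)
  reps <- lapply(1:3, function(i) {
    n <- sample(c(1000L, 5000L, 20000L), 1)
    draw <- as.integer(rmultinom(1, n, probs))
    sc(barcode = "b1", call = names(probs), indel_size = c(0L, -7L, 1L),
       reads = draw)
  })
  avg <- normalize_replicates(reps)
  expect_true(all(abs(avg$proportion - probs[avg$call]) <
                    3 * sqrt(probs[avg$call] * (1 - probs[avg$call]) / 1000)))
  zero <- sc(barcode = "b1", call = "wt", indel_size = 0L, reads = 0L)
  expect_warning(normalize_replicates(list(r1, zero)), "zero total")
})

test_that("pathway classification computes the MMEJ:NHEJ balance", {
  tab <- sc(barcode = rep("b1", 3), call = c("del", "ins", "wt"),
            indel_size = c(-7L, 1L, 0L), reads = c(30L, 70L, 900L))
  s <- classify_pathways(tab)
  expect_equal(s$mmej_count, 30L)
  expect_equal(s$nhej_count, 70L)
  expect_equal(s$mmej_fraction, 0.30)
  expect_equal(s$total_indel_reads, 100L)    # wild-type excluded

  only_ins <- sc(barcode = "b1", call = "ins", indel_size = 1L, reads = 50L)
  expect_equal(classify_pathways(only_ins)$mmej_fraction, 0)

  none <- sc(barcode = "b1", call = "wt", indel_size = 0L, reads = 50L)
  expect_true(is.na(classify_pathways(none)$mmej_fraction))

  ## depth-scaling invariance
  tab10 <- tab; tab10$reads <- tab$reads * 10L
  expect_equal(classify_pathways(tab10)$mmej_fraction, s$mmej_fraction)

  ## detail mode: -7 deletions without the 3 bp microhomology are 'other'
  detail <- data.frame(barcode = "b1", indel_size = -7L,
                       microhomology_len = 0L, reads = 30L)
  sd <- classify_pathways(tab, detail = detail)
  expect_equal(sd$mmej_count, 0L)
  expect_equal(sd$other_count, 30L)
  detail$microhomology_len <- 3L
  expect_equal(classify_pathways(tab, detail = detail)$mmej_count, 30L)

  expect_error(pathway_rules(mmej_signatures = data.frame(indel_size = 1L,
                                                          mh_len = NA),
                             nhej_signatures = 1L), "disjoint")
})

test_that("the rank-sum test agrees with exact enumeration for small groups", {
  withr::local_seed(45)
  for (i in 1:40) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- runif(nx); y <- runif(ny) - sample(c(0, 0.3), 1)
    p_pkg <- suppressWarnings(
      stats::wilcox.test(y, x, alternative = "less", exact = TRUE)$p.value)
    expect_equal(p_pkg, wilcox_enum_less(y, x), tolerance = 1e-12)
  }
})

test_that("inhibitor suppression labels NHEJ types and respects the ratio floor", {
  withr::local_seed(55)
  n_bc <- 50
  dmso <- data.frame(indel_type = "ins_1", unit = sprintf("b%02d", 1:n_bc),
                     ratio = pmax(rnorm(n_bc, 0.2, 0.04), 0.01))
  inhib <- dmso
  inhib$ratio <- dmso$ratio / 10 * exp(rnorm(n_bc, 0, 0.2))
  ## a rare type below the vehicle floor is never tested
  dmso2 <- rbind(dmso, data.frame(indel_type = "del_33",
                                  unit = dmso$unit, ratio = 0.005))
  inhib2 <- rbind(inhib, data.frame(indel_type = "del_33",
                                    unit = dmso$unit, ratio = 0.004))
  res <- classify_nhej_by_inhibitor(dmso2, inhib2)
  expect_true(res$nhej[res$indel_type == "ins_1"])
  expect_false(res$tested[res$indel_type == "del_33"])
  expect_false(res$nhej[res$indel_type == "del_33"])

  ## too few replicates: untested, not guessed
  tiny <- classify_nhej_by_inhibitor(dmso[1:2, ], inhib[1:2, ])
  expect_false(tiny$tested)

  ## identical distributions rarely get labelled after BH adjustment
  n_types <- 200
  null_d <- data.frame(
    indel_type = rep(sprintf("t%03d", 1:n_types), each = 10),
    unit = rep(sprintf("b%02d", 1:10), n_types),
    ratio = runif(10 * n_types, 0.05, 0.3))
  null_i <- null_d
  null_i$ratio <- runif(10 * n_types, 0.05, 0.3)
  nr <- classify_nhej_by_inhibitor(null_d, null_i)
  expect_lte(mean(nr$nhej), 0.05)
})

test_that("pool summaries join balances to pass-filtered locations", {
  summary <- data.frame(barcode = c("b1", "b2", "b3"),
                        total_reads = 100L, total_indel_reads = 50L,
                        mmej_count = 20L, nhej_count = 30L, other_count = 0L,
                        mmej_fraction = 0.4, stringsAsFactors = FALSE)
  calls <- data.frame(barcode = c("b1", "b2", "b4"),
                      chrom = "chr1", pos = 1:3, strand = "+",
                      status = c("pass", "fail", "pass"),
                      reasons = c("", "min_reads", ""),
                      stringsAsFactors = FALSE)
  j <- summarize_pool(summary, calls)
  expect_equal(j$barcode, "b1")
  expect_equal(attr(j, "n_unmapped"), 2L)   # b2 (failed) and b3
  expect_equal(attr(j, "n_no_scars"), 1L)   # b4
  empty <- summarize_pool(summary[0, ], calls)
  expect_equal(nrow(empty), 0L)
})
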