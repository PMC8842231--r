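mk_read <- function(barcode, chrom, pos, strand = "+", mapq = 42L,
                    ref_len = 100L, clip = 0L, clipped = NA_character_,
                    id = "r") {
  data.frame(read_id = id, barcode = barcode, mate = "r2", chrom = chrom,
             pos = pos, strand = strand, mapq = mapq, ref_len = ref_len,
             leading_softclip_len = clip, clipped_seq = clipped,
             stringsAsFactors = FALSE)
}

test_that("soft-clip triage keeps, discards or realigns by clip length", {
  r <- rbind(mk_read("b", "chr1", 100, clip = 0L),
             mk_read("b", "chr1", 100, clip = 10L, clipped = strrep("A", 10)),
             mk_read("b", "chr1", 100, clip = 16L, clipped = strrep("A", 16)),
             mk_read("b", "chr1", 100, clip = 20L, clipped = strrep("A", 20)))
  tr <- triage_softclip(r, threshold = 16L)
  expect_equal(tr$triage, c("keep", "discard", "discard", "realign"))
  bad <- mk_read("b", "chr1", 100, clip = 20L, clipped = NA_character_)
  expect_error(triage_softclip(bad), "clipped sequence absent")
})

test_that("locations aggregate to deterministic top-2 groups", {
  one <- do.call(rbind, lapply(1:10, function(i)
    mk_read("bc1", "chr1", 500L, id = paste0("r", i))))
  t1 <- aggregate_locations(one)
  expect_equal(t1$reads1, 10L)
  expect_true(is.na(t1$chrom2))
  expect_equal(t1$total_reads, 10L)

  two <- rbind(do.call(rbind, lapply(1:8, function(i)
                 mk_read("bc1", "chr1", 500L, id = paste0("a", i)))),
               do.call(rbind, lapply(1:2, function(i)
                 mk_read("bc1", "chr2", 900L, id = paste0("b", i)))))
  t2 <- aggregate_locations(two)
  expect_equal(c(t2$chrom1, t2$chrom2), c("chr1", "chr2"))
  expect_equal(c(t2$reads1, t2$reads2), c(8L, 2L))
  expect_equal(t2$total_reads, 10L)

  ## +/-2 bp jitter collapses into one location
  jit <- do.call(rbind, lapply(c(500L, 501L, 502L, 500L), function(p)
    mk_read("bc1", "chr1", p, id = paste0("j", p, runif(1)))))
  tj <- aggregate_locations(jit)
  expect_equal(tj$reads1, 4L)
  expect_equal(tj$pos1, 500L)   # most common position represents the group

  ## exact count/mapq tie breaks by chrom then pos
  tie <- rbind(mk_read("bc1", "chr2", 100L, id = "t1"),
               mk_read("bc1", "chr1", 900L, id = "t2"))
  tt <- aggregate_locations(tie)
  expect_equal(tt$chrom1, "chr1")
})

test_that("junction coordinates are strand-aware", {
  minus <- do.call(rbind, lapply(1:5, function(i)
    mk_read("bc1", "chr1", 401L, strand = "-", ref_len = 100L,
            id = paste0("m", i))))
  tm <- aggregate_locations(minus)
  expect_equal(tm$pos1, 500L)   # rightmost aligned base on the minus strand
  expect_equal(tm$strand1, "-")
})

test_that("integration filters enforce each threshold and match the predicate oracle", {
  p <- pipeline_params()
  few <- random_mapping_table(1)
  few$reads1 <- 4L; few$reads2 <- NA_integer_; few$total_reads <- 4L
  few$mapq_sum1 <- 4 * 30
  c1 <- filter_locations(few, p)
  expect_equal(c1$status, "fail")
  expect_match(c1$reasons, "min_reads")

  good <- few
  good$reads1 <- 100L; good$mapq_sum1 <- 3000; good$total_reads <- 100L
  expect_equal(filter_locations(good, p)$status, "pass")

  withr::local_seed(51)
  tab <- random_mapping_table(1000)
  calls <- filter_locations(tab, p)
  expect_identical(calls$status, filter_oracle(tab, p))
  ## every failing row carries at least one reason
  expect_true(all(nzchar(calls$reasons[calls$status == "fail"])))
  expect_true(all(calls$reasons[calls$status == "pass"] == ""))
})

test_that("filtering is monotone in primary-location support", {
  withr::local_seed(61)
  tab <- random_mapping_table(300)
  p <- pipeline_params()
  before <- filter_locations(tab, p)$status
  ## add reads at the primary location at its current average quality
  delta <- 10L
  tab2 <- tab
  tab2$mapq_sum1 <- tab$mapq_sum1 + delta * tab$mapq_sum1 / tab$reads1
  tab2$reads1 <- tab$reads1 + delta
  tab2$total_reads <- tab$total_reads + delta
  after <- filter_locations(tab2, p)$status
  expect_false(any(before == "pass" & after == "fail"))
})

test_that("a 50/50 split between two loci fails the primary-fraction rule", {
  split2 <- rbind(do.call(rbind, lapply(1:5, function(i)
                    mk_read("bc1", "chr1", 500L, id = paste0("a", i)))),
                  do.call(rbind, lapply(1:5, function(i)
                    mk_read("bc1", "chr2", 900L, id = paste0("b", i)))))
  tab <- aggregate_locations(split2)
  call <- filter_locations(tab, pipeline_params())
  expect_equal(call$status, "fail")
  expect_match(call$reasons, "primary_frac")
  expect_match(call$reasons, "secondary_frac")
})

test_that("chimeric alignments realign to the true flank and truth is recovered", {
  cfg <- simulation_config(seed = 71, n_integrations = 100, ipcr_depth = 20,
                           chimera_rate = 0.01, substitution_error_rate = 0,
                           barcode_mutation_rate = 0)
  ip <- simulate_ipcr(test_spec, cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(ip$sam, ip$genome, sam)
  aln <- read_alignments(sam)
  expect_setequal(unique(aln$mate), c("r1", "r2"))
  r2 <- triage_softclip(aln[aln$mate == "r2", ])
  kept <- rbind(r2[r2$triage == "keep", ],
                realign_clipped(r2, ip$genome))
  tab <- aggregate_locations(kept)
  m <- merge(tab, ip$integrations, by = "barcode")
  expect_equal(nrow(m), 100L)
  expect_true(all(m$chrom1 == m$chrom & m$pos1 == m$pos &
                  m$strand1 == m$strand))
  ## error-free depth >= 5 and no cross-mapping: all barcodes pass
  calls <- filter_locations(tab, pipeline_params())
  expect_true(all(calls$status == "pass"))
})

test_that("barcodes can come from the read name instead of a tag", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:chr1\tLN:1000",
               paste("q1_AAGGCCAAGGCCAAGG", 129, "chr1", 100, 42, "50M",
                     "*", 0, 0, strrep("A", 50), strrep("I", 50), sep = "\t")),
             sam)
  aln <- read_alignments(sam, barcode_in = "qname")
  expect_equal(aln$barcode, "AAGGCCAAGGCCAAGG")
  expect_equal(aln$ref_len, 50L)
})
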