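## Independent oracles used across the suite. These deliberately do not
## share code with the package implementation.

## full dynamic-programming edit-distance matrix
lev_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m))
    for (j in seq_len(n))
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (A[i] != B[j]))
  d[m + 1L, n + 1L]
}

## brute-force single-linkage clustering: link every pair at distance
## <= max_dist, take connected components, genuine = most abundant member
## (ties broken lexicographically)
cluster_oracle <- function(counts, max_dist = 1L) {
  bcs <- names(counts)
  n <- length(bcs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    di <- utils::adist(bcs[i], bcs[(i + 1L):n])
    for (k in which(di <= max_dist)) {
      j <- i + k
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  genuine <- vapply(split(seq_len(n), roots), function(ix) {
    cnt <- counts[ix]
    nm <- bcs[ix]
    nm[order(-as.numeric(cnt), nm)][1]
  }, character(1))
  unname(sort(genuine))
}

## exact one-sided rank-sum p-value: P(rank sum of y <= observed) over all
## assignments of the pooled ranks (no ties assumed)
wilcox_enum_less <- function(y, x) {
  ny <- length(y)
  r <- rank(c(y, x))
  W <- sum(r[seq_len(ny)])
  cmb <- utils::combn(ny + length(x), ny)
  Ws <- colSums(matrix(r[cmb], nrow = ny))
  mean(Ws <= W)
}

## independent re-evaluation of the four integration-site predicates
filter_oracle <- function(tab, p) {
  vapply(seq_len(nrow(tab)), function(i) {
    r2 <- tab$reads2[i]; if (is.na(r2)) r2 <- 0L
    ok <- tab$reads1[i] >= p$min_ipcr_reads &&
      tab$mapq_sum1[i] / tab$reads1[i] > p$min_avg_mapq &&
      tab$reads1[i] / tab$total_reads[i] >= p$min_primary_frac &&
      r2 / tab$total_reads[i] <= p$max_secondary_frac
    if (ok) "pass" else "fail"
  }, character(1))
}

gini <- function(p) {
  p <- sort(p); n <- length(p)
  sum((2 * seq_len(n) - n - 1) * p) / (n * sum(p))
}

## random mapping tables for filter tests
random_mapping_table <- function(n) {
  reads1 <- sample(1:60, n, replace = TRUE)
  has2 <- runif(n) < 0.6
  reads2 <- ifelse(has2, sample(0:20, n, replace = TRUE), NA_integer_)
  reads2 <- ifelse(!is.na(reads2) & reads2 > reads1, reads1, reads2)
  extra <- sample(0:5, n, replace = TRUE)
  total <- reads1 + ifelse(is.na(reads2), 0L, reads2) + extra
  data.frame(
    barcode = sprintf("bc%05d", seq_len(n)),
    chrom1 = "chr1", pos1 = seq_len(n), strand1 = "+",
    reads1 = reads1,
    mapq_sum1 = reads1 * runif(n, 0, 42),
    chrom2 = ifelse(is.na(reads2), NA_character_, "chr2"),
    pos2 = ifelse(is.na(reads2), NA_integer_, seq_len(n)),
    strand2 = ifelse(is.na(reads2), NA_character_, "-"),
    reads2 = reads2,
    mapq_sum2 = ifelse(is.na(reads2), NA_real_, reads2 * 30),
    total_reads = total,
    stringsAsFactors = FALSE)
}

## shared small fixtures (built once per test run)
test_spec <- make_reporter(1)
noiseless_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, substitution_error_rate = 0,
                    barcode_mutation_rate = 0, chimera_rate = 0, ...)
}
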