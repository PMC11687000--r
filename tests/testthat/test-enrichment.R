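test_that("Phred/error conversion follows the closed form and inverts", {
  expect_equal(phred_from_error(0.1), 10)
  expect_equal(phred_from_error(1.0), 0)
  expect_equal(phred_from_error(0.125893), 9, tolerance = 1e-4)
  q <- seq(0.5, 60, by = 0.5)
  expect_equal(phred_from_error(error_from_phred(q)), q, tolerance = 1e-12)
  expect_error(phred_from_error(0), "0, 1")
  expect_error(phred_from_error(1.5), "0, 1")
  expect_error(error_from_phred(-1), ">= 0")
})

test_that("the read filter keeps Q >= 9 and length >= 500, boundaries inclusive", {
  reads <- tibble::tibble(
    read_id = c("short", "boundary", "lowq"),
    sample = "S1", chrom = "chr1", start = 0L,
    read_len = c(499L, 500L, 5000L),
    mean_err = c(error_from_phred(20), error_from_phred(9),
                 error_from_phred(8.9)))
  reads$end <- reads$start + reads$read_len
  fr <- filter_reads(reads)
  expect_equal(fr$kept$read_id, "boundary")
  expect_setequal(fr$removed$read_id, c("short", "lowq"))
  expect_equal(nrow(fr$kept) + nrow(fr$removed), nrow(reads))
})

test_that("the generator's planted sub-threshold reads are exactly the removed set", {
  b <- cached_bundle(seed = 2, include_reads = TRUE,
                     include_haplotypes = FALSE)
  fr <- filter_reads(b$reads)
  expect_identical(sort(fr$removed$read_id),
                   sort(b$reads$read_id[b$reads$planted_fail]))
})

test_that("on-target classification uses >= 1 bp overlap on half-open intervals", {
  regions <- tibble::tibble(chrom = "chr3", start = 48580819L,
                            end = 48780819L, name = "r1")
  reads <- tibble::tibble(
    read_id = c("partial", "inside", "abutting", "unmapped"),
    sample = "S1",
    chrom = c("chr3", "chr3", "chr3", NA),
    start = c(48580000L, 48600000L, 48570000L, 0L),
    end = c(48581000L, 48601000L, 48580819L, 1000L),
    read_len = 1000L, mean_err = 0.01)
  out <- classify_on_target(reads, regions)
  expect_true(out$on_target[out$read_id == "partial"])   # 181 bp overlap
  expect_true(out$on_target[out$read_id == "inside"])
  expect_false(out$on_target[out$read_id == "abutting"]) # zero overlap
  expect_false(out$on_target[out$read_id == "unmapped"])
  expect_true(out$unmapped[out$read_id == "unmapped"])
})

test_that("coverage is base-level: 10 x 2 kb reads in a 200 kb region give 0.1x", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L,
                            name = "r")
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:10), sample = "S1", chrom = "chr1",
    start = seq(0L, by = 15000L, length.out = 10))
  reads$end <- reads$start + 2000L
  reads$read_len <- 2000L
  reads$mean_err <- error_from_phred(20)
  qc <- sample_stats(reads, regions, genome_size = 1e6)
  on <- qc[qc$scope == "on_target", ]
  expect_equal(on$avg_cov, 0.1)
  expect_equal(on$n_reads, 10L)
  expect_equal(on$avg_len, 2000)
  expect_equal(on$avg_qual, 20)
})

test_that("a read straddling a region edge contributes only its inside bases", {
  regions <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                            name = "r")
  reads <- tibble::tibble(read_id = "r1", sample = "S1", chrom = "chr1",
                          start = 500L, end = 1500L, read_len = 1000L,
                          mean_err = 0.01)
  qc <- sample_stats(reads, regions, genome_size = 101000)
  expect_equal(qc$avg_cov[qc$scope == "on_target"], 500 / 1000)
  expect_equal(qc$avg_cov[qc$scope == "off_target"], 500 / 100000)
})

test_that("aligned bases are conserved between on- and off-target, randomised", {
  set.seed(31)
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(10000L, 50000L),
                            end = c(20000L, 60000L), name = c("a", "b"))
  for (i in 1:10) {
    n <- 200
    start <- sample.int(80000, n)
    len <- sample(100:3000, n, replace = TRUE)
    reads <- tibble::tibble(read_id = sprintf("r%d", 1:n), sample = "S1",
                            chrom = "chr1", start = start, end = start + len,
                            read_len = len, mean_err = 0.01)
    split <- nanosieve:::aligned_base_split(reads, regions)
    expect_equal(split$on_bases + split$off_bases, as.numeric(len))
    expect_true(all(split$on_bases >= 0 & split$off_bases >= 0))
  }
})

test_that("zero-read scopes are flagged with n_reads 0 and NA means", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                            name = "r")
  reads <- tibble::tibble(read_id = "r1", sample = "S1", chrom = "chr1",
                          start = 10L, end = 500L, read_len = 490L,
                          mean_err = 0.01)
  qc <- sample_stats(reads, regions, genome_size = 1e5)
  off <- qc[qc$scope == "off_target", ]
  expect_equal(off$n_reads, 0L)
  expect_true(is.na(off$avg_len))
  expect_equal(off$avg_cov, 0)
})

test_that("cohort summary reproduces the published mean and SE row", {
  cs <- cohort_summary(nanopore_run_qc())
  g <- function(scope, metric, col) {
    cs[[col]][cs$scope == scope & cs$metric == metric]
  }
  expect_equal(round_half_up(g("on_target", "avg_cov", "mean"), 2), 14.64)
  expect_equal(round_half_up(g("on_target", "avg_len", "se"), 2), 903.90)
  expect_equal(round_half_up(g("on_target", "avg_qual", "se"), 2), 0.14)
  expect_equal(round_half_up(g("on_target", "avg_cov", "se"), 2), 1.00)
  expect_equal(round_half_up(g("off_target", "avg_len", "se"), 2), 195.63)
  expect_equal(round_half_up(g("off_target", "avg_qual", "se"), 2), 0.17)
  expect_equal(round_half_up(g("off_target", "avg_cov", "se"), 2), 0.25)
})

test_that("SE equals a brute-force two-pass computation; degenerate cases flagged", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    stats <- tibble::tibble(sample = sprintf("S%d", 1:n), scope = "on_target",
                            avg_len = rnorm(n, 1e4, 1e3),
                            avg_qual = rnorm(n, 22, 0.5),
                            avg_cov = runif(n, 5, 20))
    cs <- cohort_summary(stats)
    for (m in c("avg_len", "avg_qual", "avg_cov")) {
      x <- stats[[m]]
      mu <- sum(x) / n
      s2 <- sum((x - mu)^2) / (n - 1)       # two-pass variance
      expect_equal(cs$se[cs$metric == m], sqrt(s2 / n), tolerance = 1e-9)
    }
  }
  const <- tibble::tibble(sample = c("a", "b", "c"), scope = "on_target",
                          avg_cov = c(5, 5, 5))
  expect_equal(cohort_summary(const)$se, 0)
  single <- tibble::tibble(sample = "a", scope = "on_target", avg_cov = 5)
  expect_warning(cs1 <- cohort_summary(single), "fewer than 2")
  expect_true(is.na(cs1$se))
})
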