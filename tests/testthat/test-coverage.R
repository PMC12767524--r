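# Stop-base coverage, deduplication, RPM, replicate pooling, profile
# extraction with strand flipping.

reads_dt <- function(...) {
  data.table::rbindlist(lapply(list(...), function(x)
    data.table::data.table(chrom = x[[1]], start = as.integer(x[[2]]),
                           end = as.integer(x[[3]]), strand = x[[4]],
                           fixed_barcode = x[[5]], random_barcode = x[[6]])))
}

test_that("stop base is the 5'-most aligned position per strand", {
  cov <- stop_base_coverage(reads_dt(
    list("chr1", 100, 135, "+", "AAGT", "ACGTA"),
    list("chr1", 100, 135, "-", "AAGT", "TTTTT")))
  expect_equal(promnex:::coverage_at(cov, "chr1", 100, "+"), 1)
  expect_equal(promnex:::coverage_at(cov, "chr1", 134, "-"), 1)
  expect_equal(promnex:::coverage_at(cov, "chr1", 134, "+"), 0)
  expect_equal(cov$total_signal, 2)
})

test_that("barcode deduplication counts identical reads once", {
  same <- reads_dt(list("chr1", 100, 135, "+", "AAGT", "ACGTA"),
                   list("chr1", 100, 135, "+", "AAGT", "ACGTA"))
  expect_equal(stop_base_coverage(same)$total_signal, 1)
  diff_bc <- reads_dt(list("chr1", 100, 135, "+", "AAGT", "ACGTA"),
                      list("chr1", 100, 135, "+", "AAGT", "GGGGG"))
  expect_equal(stop_base_coverage(diff_bc)$total_signal, 2)
  expect_error(stop_base_coverage(reads_dt(
    list("chr1", 135, 100, "+", "A", "B"))), "start >= end")
  expect_error(stop_base_coverage(reads_dt(
    list("chr1", 100, 135, "*", "A", "B"))), "strand")
})

test_that("deduplicated coverage is order-independent", {
  set.seed(21)
  n <- 200
  reads <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample(1000:1020, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    fixed_barcode = sample(c("CTGA", "TGAC"), n, TRUE),
    random_barcode = sample(c("AA", "AC", "AG", "AT"), n, TRUE))
  reads[, end := start + 36L]
  c1 <- stop_base_coverage(reads)
  c2 <- stop_base_coverage(reads[sample(n)])
  expect_identical(c1$cov, c2$cov)
})

test_that("RPM normalization scales to a one-million total, idempotently", {
  dt <- data.table::data.table(chrom = "chr1", pos = c(5L, 9L),
                               strand = "+", count = c(10, 2e6 - 10))
  cov <- stranded_coverage(dt)
  r <- rpm_normalize(cov)
  expect_equal(promnex:::coverage_at(r, "chr1", 5, "+"), 5)
  expect_equal(r$total_signal, 1e6)
  expect_equal(rpm_normalize(r)$total_signal, 1e6)
  empty <- stranded_coverage(dt[0])
  expect_error(rpm_normalize(empty), "empty")
})

test_that("replicate pooling averages per position with zero fill", {
  a <- stranded_coverage(data.table::data.table(
    chrom = "chr1", pos = 10L, strand = "+", count = 4))
  b <- stranded_coverage(data.table::data.table(
    chrom = "chr1", pos = 11L, strand = "+", count = 6))
  pooled <- pool_replicates(list(a, b))
  expect_equal(promnex:::coverage_at(pooled, "chr1", 10, "+"), 2)
  expect_equal(promnex:::coverage_at(pooled, "chr1", 11, "+"), 3)
  expect_identical(pool_replicates(list(a, a))$cov, a$cov)
  expect_identical(pool_replicates(list(b, b, b))$cov, b$cov)
  expect_error(pool_replicates(list()), "at least one")
})

test_that("profile extraction flips minus-strand promoters into sense", {
  cov <- stranded_coverage(data.table::data.table(
    chrom = "chr1", pos = c(990L, 1010L), strand = c("+", "+"),
    count = c(7, 7)))
  plus <- data.table::data.table(chrom = "chr1", pos = 1000L,
                                 name = "p", strand = "+")
  minus <- data.table::data.table(chrom = "chr1", pos = 1000L,
                                  name = "m", strand = "-")
  pm_p <- extract_profile_matrix(cov, plus, w = 20)
  expect_equal(unname(pm_p$sense_pos["p", "-10"]), 7)
  pm_m <- extract_profile_matrix(cov, minus, w = 20)
  # genomic + value at TSS+10 appears at sense offset -10 on the neg plane
  expect_equal(unname(pm_m$sense_neg["m", "-10"]), 7)
  expect_equal(unname(pm_m$sense_pos["m", "-10"]), 0)
  expect_error(extract_profile_matrix(cov, plus, w = 0), ">= 1")
})

test_that("a minus-strand promoter profiles like its plus-strand twin", {
  cfg <- synthetic_config(n_promoters_per_class = 1, classes = "TATA",
                          seed = 77, reads_per_factor = 400,
                          peak_sd = 1e-4, minus_strand_frac = 0)
  cfg_m <- synthetic_config(n_promoters_per_class = 1, classes = "TATA",
                            seed = 77, reads_per_factor = 400,
                            peak_sd = 1e-4, minus_strand_frac = 1)
  g_p <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  g_m <- generate_promoter_sequences(cfg_m, scrubbed = FALSE)
  stopifnot(g_p$truth$strand == "+", g_m$truth$strand == "-")
  pm_p <- extract_profile_matrix(
    simulate_stranded_footprints(g_p$truth, cfg, "TFIID"), g_p$tss, w = 50)
  pm_m <- extract_profile_matrix(
    simulate_stranded_footprints(g_m$truth, cfg_m, "TFIID"), g_m$tss, w = 50)
  expect_equal(unname(pm_p$sense_pos), unname(pm_m$sense_pos))
  expect_equal(unname(pm_p$sense_neg), unname(pm_m$sense_neg))
})

test_that("bedGraph pairs round-trip coverage exactly", {
  cfg <- tiny_config(reads_per_factor = 100)
  gen <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  cov <- simulate_stranded_footprints(gen$truth, cfg, "TBP")
  prefix <- tempfile()
  write_bedgraph_pair(rpm_normalize(cov), prefix)
  back <- read_bedgraph_pair(prefix)
  orig <- rpm_normalize(cov)
  expect_equal(back$cov$count, orig$cov$count)
  expect_equal(back$total_signal, orig$total_signal)
})
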