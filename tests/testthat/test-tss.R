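# CAGE pipeline: power-law normalization, CTSS clustering, interquantile
# boundaries, consensus aggregation, narrow-promoter selection.

test_that("power-law normalization is rank-preserving and near-identity on
           referent-law counts", {
  p <- powerlaw_params()
  lambda_ref <- p$T / promnex:::.zeta(p$alpha)
  ks <- seq_len(5e4)
  v <- (lambda_ref / ks)^(1 / p$alpha)
  v <- v[v >= p$fit_low & v <= p$fit_high]
  out <- powerlaw_normalize(v, p)
  expect_lt(max(abs(out - v) / v), 0.01)
  set.seed(4)
  counts <- rpois(500, 20) + 1
  norm <- powerlaw_normalize(counts, p)
  expect_identical(order(norm), order(counts))       # zero rank inversions
  expect_true(all(diff(norm[order(counts)]) >= 0))   # monotone
  expect_error(powerlaw_normalize(c(1, 1, 2, 2), p), "distinct")
})

test_that("CTSS clustering splits at gaps above the merge distance", {
  ctss <- data.table::data.table(chrom = "chr1", strand = "+",
                                 pos = c(100L, 120L, 160L), count = 1)
  cl <- cluster_ctss(ctss, maxdist = 30)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$positions, c(100, 120))
  expect_equal(cl[[2]]$positions, 160)
  # singleton
  cl1 <- cluster_ctss(ctss[1], maxdist = 30)
  expect_length(cl1, 1)
  # invariance to input order; strands cluster independently
  mixed <- data.table::data.table(
    chrom = "chr1", strand = c("+", "-", "+", "-"),
    pos = c(100L, 101L, 110L, 112L), count = 2)
  cl_a <- cluster_ctss(mixed, maxdist = 30)
  cl_b <- cluster_ctss(mixed[c(3, 1, 4, 2)], maxdist = 30)
  expect_equal(cl_a, cl_b)
  expect_length(cl_a, 2)
  # partition: every position in exactly one cluster, TPM conserved
  all_pos <- sort(unlist(lapply(cl_a, `[[`, "positions")))
  expect_equal(length(all_pos), nrow(mixed))
  expect_equal(sum(vapply(cl_a, `[[`, numeric(1), "tpm")), sum(mixed$count))
  expect_length(cluster_ctss(mixed[0]), 0)
})

test_that("interquantile boundaries follow the cumulative distribution", {
  mk <- function(pos, counts) list(chrom = "chr1", strand = "+",
                                   positions = pos, counts = counts,
                                   tpm = sum(counts))
  b <- interquantile_boundaries(mk(100:102, c(1, 8, 1)))
  expect_equal(c(b$q_low_pos, b$q_high_pos, b$interquantile_width),
               c(100, 101, 2))
  b1 <- interquantile_boundaries(mk(55L, 10))
  expect_equal(b1$interquantile_width, 1)
  bu <- interquantile_boundaries(mk(0:9, rep(1, 10)))
  expect_equal(c(bu$q_low_pos, bu$q_high_pos, bu$interquantile_width),
               c(0, 8, 9))
  expect_error(interquantile_boundaries(
    list(positions = integer(0), counts = numeric(0))), "empty")
})

test_that("consensus aggregation merges, filters and finds dominant TSS", {
  mk <- function(pos, counts, strand = "+")
    interquantile_boundaries(list(chrom = "chr1", strand = strand,
                                  positions = pos, counts = counts,
                                  tpm = sum(counts)))
  # replicate clusters 10 bp apart merge (10 <= 100)
  agg <- aggregate_clusters(list(list(mk(100:102, c(1, 5, 9))),
                                 list(mk(110:112, c(2, 9, 1)))))
  expect_equal(nrow(agg), 1)
  # summed signal argmax: 9 at 102 and 9 at 111 -> tie resolved 5'-most
  expect_equal(agg$dominant_tss, 102)
  # span is the union of the interquantile regions [101,111], so the
  # flanking single tags at 100 and 112 fall outside
  expect_equal(agg$tpm, 25)
  # low-TPM in all replicates -> dropped
  agg2 <- aggregate_clusters(list(list(mk(100L, 0.4)), list(mk(101L, 0.4))),
                             tpm_min = 0.5)
  expect_equal(nrow(agg2), 0)
  # passes if any replicate reaches the threshold
  agg3 <- aggregate_clusters(list(list(mk(100L, 0.4)), list(mk(101L, 0.6))),
                             tpm_min = 0.5)
  expect_equal(nrow(agg3), 1)
  # distant clusters stay separate
  agg4 <- aggregate_clusters(list(list(mk(100L, 5), mk(300L, 5))),
                             maxdist = 100)
  expect_equal(nrow(agg4), 2)
  # dominant TSS argmax on clean signal
  agg5 <- aggregate_clusters(list(list(mk(200:201, c(5, 9)))))
  expect_equal(agg5$dominant_tss, 201)
})

test_that("narrow-promoter selection applies all three filters", {
  base <- data.table::data.table(
    cluster_id = sprintf("cc_%d", 1:5), chrom = "chr1", strand = "+",
    start = c(1, 50, 100, 150, 200), end = c(20, 70, 120, 170, 220),
    q_low_pos = 0, q_high_pos = 0,
    interquantile_width = c(10L, 12L, 1L, 1L, 5L),
    dominant_tss = 1, tpm = c(8, 8, 2, 5, 3),
    n_tss = c(4L, 4L, 1L, 1L, 3L),
    gene_id = c("g1", NA, NA, NA, "g1"))
  out <- select_narrow_promoters(base)
  # width 12 dropped; single-TSS TPM 2 dropped; gene g1 keeps the TPM-8 one
  expect_setequal(out$cluster_id, c("cc_1", "cc_4"))
  # width 10 kept, width 12 dropped
  expect_true("cc_1" %in% out$cluster_id)
  expect_false("cc_2" %in% out$cluster_id)
})

test_that("gene assignment picks the nearest annotated TSS within range", {
  cl <- data.table::data.table(
    cluster_id = "cc_1", chrom = "chr1", strand = "+", start = 100,
    end = 110, q_low_pos = 100, q_high_pos = 110,
    interquantile_width = 11L, dominant_tss = 105, tpm = 5, n_tss = 5L,
    gene_id = NA_character_)
  ann <- data.table::data.table(chrom = "chr1", pos = c(100L, 700L),
                                name = c("gA", "gB"),
                                strand = c("+", "+"))
  expect_equal(assign_genes(cl, ann)$gene_id, "gA")
  ann_far <- data.table::data.table(chrom = "chr1", pos = 5000L,
                                    name = "gC", strand = "+")
  expect_true(is.na(assign_genes(cl, ann_far)$gene_id))
  ann_wrong <- data.table::data.table(chrom = "chr1", pos = 100L,
                                      name = "gD", strand = "-")
  expect_true(is.na(assign_genes(cl, ann_wrong)$gene_id))
})

test_that("narrow kernels pass the end-to-end pipeline, wide kernels fail", {
  cfg <- synthetic_config(n_promoters_per_class = 10, seed = 31,
                          cage_kernel_sd = 1)
  gen <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  res <- cage_pipeline(simulate_cage(gen$truth, cfg),
                       tss_annotation = gen$tss)
  expect_gte(nrow(res$narrow) / nrow(gen$truth), 0.95)
  expect_true(all(res$narrow$interquantile_width < 11))
  # dominant TSS inside the interquantile region on unimodal clusters
  expect_true(all(res$narrow$dominant_tss >= res$narrow$q_low_pos &
                    res$narrow$dominant_tss <= res$narrow$q_high_pos))
  cfg_w <- synthetic_config(n_promoters_per_class = 10, seed = 31,
                            cage_kernel_sd = 10)
  res_w <- cage_pipeline(simulate_cage(gen$truth, cfg_w),
                         tss_annotation = gen$tss)
  expect_lte(nrow(res_w$narrow) / nrow(gen$truth), 0.05)
})
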