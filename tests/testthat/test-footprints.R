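# Average profiles, footprint contact midpoints, min-max normalization,
# PCA module assignment.

mk_profile <- function(pos_peaks, neg_peaks, w = 50, heights = 1) {
  offsets <- -w:w
  pos <- numeric(length(offsets)); neg <- numeric(length(offsets))
  pos[match(pos_peaks, offsets)] <- heights
  neg[match(neg_peaks, offsets)] <- heights
  structure(list(factor = "x", offsets = offsets, positive_strand = pos,
                 negative_strand = neg), class = "average_profile")
}

test_that("average_profile is the per-offset mean and is linear", {
  cfg <- tiny_config(reads_per_factor = 50)
  gen <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  cov <- simulate_stranded_footprints(gen$truth, cfg, "TFIID")
  pm <- extract_profile_matrix(cov, gen$tss, w = 50)
  ap <- average_profile(pm)
  expect_equal(unname(ap$positive_strand), unname(colMeans(pm$sense_pos)))
  one <- subset_profiles(pm, 1)
  ap1 <- average_profile(one)
  expect_equal(unname(ap1$positive_strand), unname(one$sense_pos[1, ]))
  sc <- pm; sc$sense_pos <- 3 * sc$sense_pos; sc$sense_neg <- 3 * sc$sense_neg
  expect_equal(average_profile(sc)$negative_strand, 3 * ap$negative_strand)
})

test_that("midpoints are the mean of paired strand peaks", {
  p <- mk_profile(-22, -14)
  res <- detect_footprint_midpoints(p)
  expect_equal(res$midpoint, -18)
  p2 <- mk_profile(-21, -14)
  expect_equal(detect_footprint_midpoints(p2)$midpoint, -17.5)
  expect_error(detect_footprint_midpoints(mk_profile(integer(0), integer(0))),
               "all-zero")
})

test_that("midpoint detection is translation-equivariant and scale-free", {
  base <- mk_profile(c(-34, -22, 6), c(-26, -14, 14), heights = c(3, 2, 1))
  m0 <- detect_footprint_midpoints(base)$midpoint
  shifted <- mk_profile(c(-34, -22, 6) + 5, c(-26, -14, 14) + 5,
                        heights = c(3, 2, 1))
  expect_equal(detect_footprint_midpoints(shifted)$midpoint, m0 + 5)
  scaled <- base
  scaled$positive_strand <- 7.3 * scaled$positive_strand
  scaled$negative_strand <- 7.3 * scaled$negative_strand
  expect_equal(detect_footprint_midpoints(scaled)$midpoint, m0)
})

test_that("unpaired peaks are reported with NA partners", {
  p <- mk_profile(-22, 30)  # negative peak 52 bp downstream: beyond pairing
  res <- detect_footprint_midpoints(p, max_pair_distance = 40)
  expect_true(all(is.na(res$midpoint)))
  expect_equal(nrow(res), 2)
})

test_that("minmax_normalize maps to [0,1] and flags constant input", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(as.numeric(out), c(0, 0, 0))
  expect_true(attr(out, "constant"))
  set.seed(9)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
  expect_error(minmax_normalize(1), "at least 2")
})

test_that("PCA coordinates match an eigendecomposition oracle", {
  set.seed(12)
  profiles <- lapply(1:6, function(i) {
    mu <- c(-30, -18, 10, 19, 32)[(i %% 3) + 1]
    offs <- -50:50
    structure(list(factor = paste0("f", i), offsets = offs,
                   positive_strand = dnorm(offs, mu - 4, 3) + runif(101, 0, 1e-3),
                   negative_strand = dnorm(offs, mu + 4, 3) + runif(101, 0, 1e-3)),
              class = "average_profile")
  })
  names(profiles) <- paste0("f", 1:6)
  res <- pca_modules(profiles, n_modules = 2, seed = 3)
  expect_equal(sum(res$explained), 1)
  # oracle: centered data times eigenvectors of the covariance matrix
  feats <- t(vapply(profiles, function(p)
    minmax_normalize(c(p$positive_strand, p$negative_strand)), numeric(202)))
  ctr <- scale(feats, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(ctr))
  oracle <- ctr %*% ev$vectors
  for (k in 1:3) {
    a <- res$scores[, k]; b <- oracle[, k]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("identical factors land in the same module", {
  offs <- -50:50
  mk <- function(mu) structure(
    list(factor = "f", offsets = offs,
         positive_strand = dnorm(offs, mu - 4, 2),
         negative_strand = dnorm(offs, mu + 4, 2)),
    class = "average_profile")
  profiles <- list(a1 = mk(-18), a2 = mk(-18), b1 = mk(30), b2 = mk(30),
                   c1 = mk(0), c2 = mk(0), d1 = mk(-40), d2 = mk(-40))
  res <- pca_modules(profiles, n_modules = 4, seed = 2)
  asg <- res$assignments
  expect_equal(asg[factor == "a1", module_id], asg[factor == "a2", module_id])
  expect_equal(asg[factor == "b1", module_id], asg[factor == "b2", module_id])
  expect_equal(res$scores["a1", ], res$scores["a2", ])
  # planted grouping fully recovered across the 4 duplicated archetypes
  planted <- rep(1:4, each = 2)
  expect_equal(rand_index(planted, asg$module_id), 1)
  expect_error(pca_modules(profiles[1:3], n_modules = 4), "at least as many")
})
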