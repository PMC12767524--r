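# Paused-promoter selection, exponential half-life fitting, quintiles.

# flat base level inside [-50,50] sets the average; tall spikes at the
# requested offsets set the strand maxima (geometry) independently
mk_polii_matrix <- function(avg, pos_off, neg_off, w = 100) {
  offsets <- -w:w
  base <- avg / 2
  sp <- matrix(0, 1, length(offsets), dimnames = list("p1", offsets))
  sp[1, offsets >= -50 & offsets <= 50] <- base
  sn <- sp
  sp[1, as.character(pos_off)] <- base * 2
  sn[1, as.character(neg_off)] <- base * 2
  structure(list(promoter_ids = "p1", offsets = offsets,
                 sense_pos = sp, sense_neg = sn, w = w),
            class = "profile_matrix")
}

test_that("selection applies the three footprint criteria conjunctively", {
  ok <- select_paused_promoters(mk_polii_matrix(25, 10, 70))
  expect_true(ok$passes_filters)       # avg 25, distance 60, pause +40
  expect_equal(ok$pause_position, 40)
  low <- select_paused_promoters(mk_polii_matrix(10, 10, 70))
  expect_false(low$passes_filters)     # avg 10 fails regardless of geometry
  wide <- select_paused_promoters(mk_polii_matrix(25, -10, 80))
  expect_false(wide$passes_filters)    # strand distance 90
  far <- select_paused_promoters(mk_polii_matrix(25, 60, 100))
  expect_false(far$passes_filters)     # pause at +80, not < 80
})

test_that("relaxing any single threshold only grows the selected set", {
  set.seed(41)
  cfg <- synthetic_config(n_promoters_per_class = 8, seed = 19,
                          reads_per_factor = 3000, background_rate = 0.2)
  gen <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  cov <- simulate_stranded_footprints(gen$truth, cfg, "polii")
  pm <- extract_profile_matrix(cov, gen$tss, w = 100)
  base <- select_paused_promoters(pm)
  for (args in list(list(min_avg_signal = 5),
                    list(max_strand_distance = 120),
                    list(max_downstream = 120))) {
    relaxed <- do.call(select_paused_promoters, c(list(pm), args))
    expect_true(all(base[passes_filters == TRUE, promoter_id] %in%
                      relaxed[passes_filters == TRUE, promoter_id]))
  }
})

test_that("half-life fit is exact on noiseless data and floors at 60", {
  est <- fit_half_life(list(minutes = c(0, 10, 20),
                            signal = c(100, 50, 25)))
  expect_lt(abs(est$half_life_min - 10), 1e-6)
  expect_false(est$floored)
  t <- c(0, 10, 20, 40)
  est80 <- fit_half_life(list(minutes = t, signal = 100 * 2^(-t / 80)))
  expect_equal(est80$half_life_min, 60)
  expect_true(est80$floored)
  # engages exactly at the floor boundary
  est59 <- fit_half_life(list(minutes = t, signal = 100 * 2^(-t / 59.9)))
  expect_false(est59$floored)
  # scale invariance in s0
  est_sc <- fit_half_life(list(minutes = c(0, 10, 20),
                               signal = 1e4 * c(100, 50, 25)))
  expect_lt(abs(est_sc$half_life_min - 10), 1e-6)
  expect_error(fit_half_life(list(minutes = c(0, 10), signal = c(1, 2))),
               "3 timepoints")
  expect_error(fit_half_life(list(minutes = c(0, 5, 10),
                                  signal = c(0, 0, 0))), "all-zero")
})

test_that("simulated time courses round-trip through the fitter", {
  cfg <- synthetic_config(n_promoters_per_class = 4, seed = 27,
                          reads_per_factor = 10000)
  gen <- generate_promoter_sequences(cfg, scrubbed = FALSE)
  pp <- stats::setNames(
    vapply(gen$truth$contacts, function(x) x$polii[1], numeric(1)),
    gen$truth$promoter_id)
  tc0 <- simulate_pausing_timecourse(gen$truth, c(0, 5, 10, 20, 40), cfg,
                                     noise = "none")
  hl0 <- fit_half_lives(pause_window_signal(tc0, gen$tss, pp))
  truth_fl <- pmin(gen$truth$half_life_min, 60)
  m0 <- hl0[match(gen$truth$promoter_id, promoter_id)]
  expect_lt(max(abs(m0$half_life_min - truth_fl) / truth_fl), 1e-6)
  tc1 <- simulate_pausing_timecourse(gen$truth, c(0, 5, 10, 20, 40), cfg,
                                     noise = "poisson")
  hl1 <- fit_half_lives(pause_window_signal(tc1, gen$tss, pp))
  m1 <- hl1[match(gen$truth$promoter_id, promoter_id)]
  expect_lt(stats::median(abs(m1$half_life_min - truth_fl) / truth_fl), 0.10)
})

test_that("quintile binning is contiguous with remainder to outer bins", {
  mk <- function(n) data.table::data.table(
    promoter_id = sprintf("p%04d", 1:n), half_life_min = seq_len(n))
  q10 <- assign_quintiles(mk(10))
  expect_equal(as.vector(table(q10$quintile)), rep(2, 5))
  q1307 <- assign_quintiles(mk(1307))
  expect_equal(as.vector(table(q1307$quintile)), c(262, 261, 261, 261, 262))
  # monotone boundaries
  agg <- q1307[, .(lo = min(half_life_min), hi = max(half_life_min)),
               by = quintile]
  expect_true(all(agg$hi[-5] <= agg$lo[-1]))
  expect_error(assign_quintiles(mk(4)), "at least 5")
})
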