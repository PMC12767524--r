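# Paused Pol II kinetics: promoter selection by footprint criteria,
# exponential-decay half-life fitting with a 60-minute floor, and quintile
# binning.

#' Select promoters with a paused Pol II footprint
#'
#' A promoter passes when 1) its average signal over [-50, +50] (both
#' strands, per position) exceeds `min_avg_signal`; 2) the distance from
#' the positive-strand maximum to the negative-strand maximum is in
#' (0, max_strand_distance); and 3) the pause position (midpoint of the two
#' strand maxima) lies less than `max_downstream` bp downstream of the TSS.
#'
#' @param matrix `profile_matrix` of Pol II signal.
#' @param min_avg_signal average-signal threshold (20).
#' @param max_strand_distance maximum strand-peak distance in bp (80).
#' @param max_downstream maximum pause position in bp (80).
#' @param avg_window window over which the average is taken, c(-50, 50).
#' @return data.table (promoter_id, avg_signal, pos_max_offset,
#'   neg_max_offset, pause_position, passes_filters).
#' @export
select_paused_promoters <- function(matrix, min_avg_signal = 20,
                                    max_strand_distance = 80,
                                    max_downstream = 80,
                                    avg_window = c(-50, 50)) {
  if (avg_window[1] < -matrix$w || avg_window[2] > matrix$w)
    stop("matrix does not span the averaging window")
  cols <- which(matrix$offsets >= avg_window[1] &
                  matrix$offsets <= avg_window[2])
  rows <- lapply(seq_along(matrix$promoter_ids), function(i) {
    pos <- matrix$sense_pos[i, ]; neg <- matrix$sense_neg[i, ]
    avg <- mean(pos[cols] + neg[cols])
    pmax_off <- matrix$offsets[which.max(pos)]
    nmax_off <- matrix$offsets[which.max(neg)]
    pause <- (pmax_off + nmax_off) / 2
    dist <- nmax_off - pmax_off
    data.table::data.table(
      promoter_id = matrix$promoter_ids[i], avg_signal = avg,
      pos_max_offset = pmax_off, neg_max_offset = nmax_off,
      pause_position = pause,
      passes_filters = avg > min_avg_signal &
        dist > 0 & dist < max_strand_distance &
        pause < max_downstream)
  })
  data.table::rbindlist(rows)
}

#' Fit an exponential-decay half-life
#'
#' Least-squares fit of s(t) = s0 * 2^(-t / h) with s0, h > 0, initialized
#' from the log-linear closed form and refined by Levenberg-Marquardt
#' nonlinear least squares. Fits with h above `floor_min` are floored to
#' `floor_min` (flag `floored`); a failed nonlinear refinement falls back
#' to the log-linear estimate (flag `fallback`).
#'
#' @param timecourse data.frame/list with `minutes` and `signal`, at least
#'   3 timepoints including t = 0; signals >= 0.
#' @param floor_min half-life ceiling in minutes (60).
#' @return list(half_life_min, floored, s0, fit_rss, fallback).
#' @export
fit_half_life <- function(timecourse, floor_min = 60) {
  t <- timecourse$minutes; s <- timecourse$signal
  if (length(t) < 3) stop("need at least 3 timepoints")
  if (!0 %in% t) stop("timepoints must include 0")
  if (all(s == 0)) stop("all-zero signal")
  if (any(s < 0)) stop("signals must be non-negative")
  # log-linear initialization on the positive observations
  pos <- s > 0
  fit0 <- stats::lm(log2(s[pos]) ~ t[pos])
  slope <- unname(stats::coef(fit0)[2])
  h0 <- if (is.na(slope) || slope >= 0) 10 * floor_min else -1 / slope
  s0_0 <- 2^unname(stats::coef(fit0)[1])
  fallback <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * 2^(-t / h),
                      start = list(s0 = s0_0, h = min(h0, 100 * floor_min)),
                      lower = c(1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    h <- h0; s0 <- s0_0
    rss <- sum((s - s0 * 2^(-t / h))^2)
  } else {
    cf <- stats::coef(fit)
    h <- unname(cf["h"]); s0 <- unname(cf["s0"])
    rss <- sum(stats::resid(fit)^2)
  }
  floored <- h > floor_min
  if (floored) h <- floor_min
  list(half_life_min = h, floored = floored, s0 = s0, fit_rss = rss,
       fallback = fallback)
}

#' Measure a pause-window time course from coverage
#'
#' Sums signal (both strands) in a window of `window_width` bp centered on
#' each promoter's pause position, per timepoint.
#'
#' @param timecourse named list of `stranded_coverage` (names = minutes).
#' @param tss TSS table (chrom, pos, name, strand).
#' @param pause_positions named numeric vector promoter_id -> TSS-relative
#'   pause position.
#' @param window_width window size in bp (51).
#' @return data.table (promoter_id, minutes, signal).
#' @export
pause_window_signal <- function(timecourse, tss, pause_positions,
                                window_width = 51) {
  halfw <- (window_width - 1) %/% 2
  tss <- data.table::as.data.table(tss)
  rows <- list()
  for (tp in names(timecourse)) {
    w <- max(abs(c(min(pause_positions) - halfw,
                   max(pause_positions) + halfw)))
    pm <- extract_profile_matrix(timecourse[[tp]], tss, w = ceiling(w))
    for (i in seq_along(pm$promoter_ids)) {
      id <- pm$promoter_ids[i]
      ctr <- round(pause_positions[[id]])
      cols <- which(pm$offsets >= ctr - halfw & pm$offsets <= ctr + halfw)
      rows[[length(rows) + 1]] <- data.table::data.table(
        promoter_id = id, minutes = as.numeric(tp),
        signal = sum(pm$sense_pos[i, cols]) + sum(pm$sense_neg[i, cols]))
    }
  }
  data.table::rbindlist(rows)
}

#' Fit half-lives for many promoters
#'
#' @param signals data.table from [pause_window_signal()].
#' @param floor_min half-life ceiling (60).
#' @return data.table (promoter_id, half_life_min, floored, fit_rss).
#' @export
fit_half_lives <- function(signals, floor_min = 60) {
  rows <- lapply(split(signals, by = "promoter_id", sorted = TRUE),
                 function(g) {
    est <- fit_half_life(list(minutes = g$minutes, signal = g$signal),
                         floor_min = floor_min)
    data.table::data.table(promoter_id = g$promoter_id[1],
                           half_life_min = est$half_life_min,
                           floored = est$floored, fit_rss = est$fit_rss)
  })
  data.table::rbindlist(rows)
}

#' Assign half-life quintiles
#'
#' Promoters are ranked ascending by half-life (ties broken by promoter id)
#' and split into 5 contiguous bins. A remainder r is distributed to the
#' outermost bins first (bins 1 and 5, then 2 and 4), so n = 1307 gives
#' sizes (262, 261, 261, 261, 262).
#'
#' @param half_lives data.table with promoter_id and half_life_min.
#' @return the table with a `quintile` column, sorted by half-life.
#' @export
assign_quintiles <- function(half_lives) {
  n <- nrow(half_lives)
  if (n < 5) stop("need at least 5 promoters")
  base <- n %/% 5L
  r <- n - 5L * base
  sizes <- rep(base, 5L)
  extra_order <- c(1L, 5L, 2L, 4L, 3L)
  if (r > 0) sizes[extra_order[seq_len(r)]] <- base + 1L
  out <- data.table::as.data.table(half_lives)[
    order(half_life_min, promoter_id)]
  out[, quintile := rep(seq_len(5L), times = sizes)]
  out[]
}
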