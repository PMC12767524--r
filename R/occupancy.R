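# Transcription-normalized occupancy, between-type rank-sum tests,
# binding-level correlation with Ward clustering, and condition-difference
# correlations for upstream vs downstream TBP.

#' Normalize ChIP-nexus signal by CAGE expression
#'
#' In "occupancy" mode, the scalar occupancy of a promoter is its total
#' signal (both strands) over the offsets in `window` divided by its CAGE
#' score. In "profile" mode every base value is divided by the CAGE score.
#' Promoters with a missing or non-positive CAGE score are excluded (their
#' count is reported via attribute `n_excluded`).
#'
#' @param matrix `profile_matrix`.
#' @param cage named numeric vector promoter_id -> CAGE TPM.
#' @param mode "occupancy" or "profile".
#' @param window inclusive offset window for occupancy mode, c(-50, 50).
#' @return occupancy mode: data.table(promoter_id, raw_signal, cage_score,
#'   normalized); profile mode: `profile_matrix` with scaled planes.
#' @export
cage_normalize <- function(matrix, cage, mode = c("occupancy", "profile"),
                           window = c(-50, 50)) {
  mode <- match.arg(mode)
  score <- cage[matrix$promoter_ids]
  ok <- !is.na(score) & score > 0
  n_excluded <- sum(!ok)
  if (mode == "profile") {
    out <- subset_profiles(matrix, which(ok))
    out$sense_pos <- out$sense_pos / score[ok]
    out$sense_neg <- out$sense_neg / score[ok]
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  cols <- which(matrix$offsets >= window[1] & matrix$offsets <= window[2])
  raw <- rowSums(matrix$sense_pos[, cols, drop = FALSE]) +
    rowSums(matrix$sense_neg[, cols, drop = FALSE])
  out <- data.table::data.table(promoter_id = matrix$promoter_ids[ok],
                                raw_signal = raw[ok],
                                cage_score = as.numeric(score[ok]))
  out[, normalized := raw_signal / cage_score]
  attr(out, "n_excluded") <- n_excluded
  out[]
}

#' Compare normalized occupancy between promoter types
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups; all
#' observations enter the test (outlier trimming is a plotting concern
#' only).
#'
#' @param values numeric occupancies.
#' @param groups group label per value.
#' @return data.table (group1, group2, n1, n2, p).
#' @export
compare_types <- function(values, groups) {
  lv <- unique(groups)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    x <- values[groups == lv[i]]; y <- values[groups == lv[j]]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 observations per group")
    p <- stats::wilcox.test(x, y, exact = NULL)$p.value
    rows[[length(rows) + 1]] <- data.table::data.table(
      group1 = lv[i], group2 = lv[j], n1 = length(x), n2 = length(y), p = p)
  }
  data.table::rbindlist(rows)
}

#' Pairwise binding correlation and Ward clustering of factors
#'
#' Signal sums are log2(x + 1)-transformed, Pearson-correlated per factor
#' pair, converted to the distance 1 - r, and hierarchically clustered with
#' Ward's D linkage (un-squared input). Constant factor columns are
#' excluded with a warning.
#'
#' @param signal_table numeric matrix promoters x factors of window sums.
#' @return list(r = correlation matrix, distance = 1 - r, hclust = Ward
#'   dendrogram, newick = Newick string).
#' @export
binding_correlation <- function(signal_table) {
  if (nrow(signal_table) < 3 || ncol(signal_table) < 2)
    stop("need >= 3 promoters and >= 2 factors")
  lg <- log2(signal_table + 1)
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant factor column(s): ",
            paste(colnames(lg)[sds == 0], collapse = ","))
    lg <- lg[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(lg, method = "pearson")
  d <- 1 - r
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(r = r, distance = d, hclust = hc, newick = nwk)
}

#' Condition difference of TBP-TAF correlations
#'
#' For each target window, TBP signal is summed per promoter in that window
#' (both strands) and Pearson-correlated with each TAF's total signal;
#' delta PCC = r_control - r_treated.
#'
#' @param control_matrices named list factor -> `profile_matrix` (control
#'   condition); must contain `tbp_factor`.
#' @param treated_matrices same structure for the treated condition, same
#'   promoters.
#' @param tbp_factor name of the TBP entry (default "TBP").
#' @param target_windows named list of inclusive offset windows, default
#'   upstream [-25,-10] and downstream [+25,+40].
#' @param taf_window window for the TAF total signal, c(-50, 50).
#' @return data.table (window, factor, r_control, r_treated, delta_pcc).
#' @export
delta_correlation <- function(control_matrices, treated_matrices,
                              tbp_factor = "TBP",
                              target_windows = list(upstream = c(-25, -10),
                                                    downstream = c(25, 40)),
                              taf_window = c(-50, 50)) {
  stopifnot(tbp_factor %in% names(control_matrices),
            tbp_factor %in% names(treated_matrices))
  ids <- control_matrices[[tbp_factor]]$promoter_ids
  if (!identical(ids, treated_matrices[[tbp_factor]]$promoter_ids))
    stop("mismatched promoter sets between conditions")
  wsum <- function(m, win) {
    cols <- which(m$offsets >= win[1] & m$offsets <= win[2])
    rowSums(m$sense_pos[, cols, drop = FALSE]) +
      rowSums(m$sense_neg[, cols, drop = FALSE])
  }
  tafs <- setdiff(names(control_matrices), tbp_factor)
  rows <- list()
  for (wn in names(target_windows)) {
    win <- target_windows[[wn]]
    tbp_c <- wsum(control_matrices[[tbp_factor]], win)
    tbp_t <- wsum(treated_matrices[[tbp_factor]], win)
    for (f in tafs) {
      rc <- stats::cor(tbp_c, wsum(control_matrices[[f]], taf_window))
      rt <- stats::cor(tbp_t, wsum(treated_matrices[[f]], taf_window))
      rows[[length(rows) + 1]] <- data.table::data.table(
        window = wn, factor = f, r_control = rc, r_treated = rt,
        delta_pcc = rc - rt)
    }
  }
  data.table::rbindlist(rows)
}
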