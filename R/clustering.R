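# Clustering of individual promoters by TBP profile shape: top-signal
# selection, per-promoter rank transform, seeded k-means, and per-cluster
# core-promoter-element enrichment (Fisher's exact test, BH correction).

#' Select the top promoters by total signal in a TSS window
#'
#' Promoters are ranked by their total signal (both strands) inside
#' `window`; the bottom (1 - quantile_keep) fraction is dropped. Ties at
#' the cut are kept.
#'
#' @param matrix `profile_matrix`.
#' @param quantile_keep fraction retained (0.9).
#' @param window inclusive offset range, default c(-40, 40) (81 bp).
#' @return `profile_matrix` restricted to the retained promoters.
#' @export
select_top_signal <- function(matrix, quantile_keep = 0.9,
                              window = c(-40, 40)) {
  if (window[1] < -matrix$w || window[2] > matrix$w)
    stop("window exceeds matrix span")
  cols <- which(matrix$offsets >= window[1] & matrix$offsets <= window[2])
  totals <- rowSums(matrix$sense_pos[, cols, drop = FALSE]) +
    rowSums(matrix$sense_neg[, cols, drop = FALSE])
  n_keep <- ceiling(length(totals) * quantile_keep - 1e-9)
  n_drop <- length(totals) - n_keep
  if (n_drop == 0) return(matrix)
  # inclusive tie rule: promoters tied with the last retained total stay
  threshold <- sort(totals, decreasing = TRUE)[length(totals) - n_drop]
  subset_profiles(matrix, which(totals >= threshold))
}

#' Per-row rank transform to (0, 1]
#'
#' Each row's values are replaced by their ranks (average ranks on ties)
#' divided by the number of columns.
#'
#' @param mat numeric matrix (rows = promoters).
#' @return matrix of the same shape with values in (0, 1].
#' @export
rank_transform <- function(mat) {
  if (ncol(mat) == 0) stop("empty rows")
  t(apply(mat, 1, function(r) rank(r, ties.method = "average") / length(r)))
}

#' Seeded k-means on rank-transformed promoter profiles
#'
#' Euclidean k-means, best of `n_starts` random initializations, at most
#' `max_iter` iterations per start. Cluster ids are relabeled by
#' descending cluster size for stability.
#'
#' @param mat rank-transformed promoters x features matrix.
#' @param k number of clusters (4).
#' @param n_starts random starts (100).
#' @param max_iter iteration cap per start (30).
#' @param seed RNG seed.
#' @return list(assignments = data.table(promoter_id, cluster),
#'   centroids = k x features matrix, k, seed, tot_withinss).
#' @export
kmeans_profiles <- function(mat, k = 4, n_starts = 100, max_iter = 30,
                            seed = 1) {
  if (nrow(mat) < k) stop("fewer rows than clusters")
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = n_starts,
                      iter.max = max_iter)
  ord <- order(-km$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  list(assignments = data.table::data.table(promoter_id = ids,
                                            cluster = relabel[km$cluster]),
       centroids = km$centers[ord, , drop = FALSE],
       k = k, seed = seed, tot_withinss = km$tot.withinss)
}

#' Core-promoter-element enrichment per cluster
#'
#' For each (cluster, element): in_fraction is the fraction of cluster
#' promoters carrying the element, out_fraction the fraction among all
#' other promoters; ratio = in/out (Inf when out is 0 and in > 0, NA for
#' 0/0). Significance from a two-sided Fisher exact test on the 2x2 table,
#' BH-corrected jointly across all (cluster, element) pairs.
#'
#' @param assignments data.table(promoter_id, cluster).
#' @param element_presence logical matrix promoters x elements (rownames =
#'   promoter ids), from zero-mismatch scans.
#' @return data.table (cluster, element, in_n, in_total, out_n, out_total,
#'   in_fraction, out_fraction, ratio, p, q).
#' @export
element_enrichment <- function(assignments, element_presence) {
  ep <- element_presence[assignments$promoter_id, , drop = FALSE]
  clusters <- sort(unique(assignments$cluster))
  rows <- list()
  for (cl in clusters) {
    inside <- assignments$cluster == cl
    n_in <- sum(inside); n_out <- sum(!inside)
    if (n_in == 0) stop("cluster of size 0")
    for (el in colnames(ep)) {
      a <- sum(ep[inside, el]); b <- n_in - a
      c_ <- sum(ep[!inside, el]); d <- n_out - c_
      in_f <- a / n_in
      out_f <- if (n_out > 0) c_ / n_out else NA_real_
      ratio <- if (is.na(out_f) || (out_f == 0 && in_f == 0)) NA_real_
      else if (out_f == 0) Inf else in_f / out_f
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                     byrow = TRUE))$p.value
      rows[[length(rows) + 1]] <- data.table::data.table(
        cluster = cl, element = el, in_n = a, in_total = n_in,
        out_n = c_, out_total = n_out, in_fraction = in_f,
        out_fraction = out_f, ratio = ratio, p = p)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, q := stats::p.adjust(p, method = "BH")]
  out[]
}
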