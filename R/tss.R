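# CAGE TSS annotation: power-law normalization, distance clustering of CTSS
# positions, interquantile boundaries, cross-replicate consensus clusters,
# dominant TSS and narrow-promoter selection.

#' Power-law normalization parameters
#'
#' Referent slope alpha = 1.19 and total T = 1e6, fitted over the raw-count
#' range 3..40000, as in standard CAGE power-law normalization.
#'
#' @param alpha referent power-law slope (> 1).
#' @param T referent library total.
#' @param fit_low,fit_high raw-count fit range.
#' @export
powerlaw_params <- function(alpha = 1.19, T = 1e6,
                            fit_low = 3, fit_high = 40000) {
  stopifnot(alpha > 1, fit_low < fit_high)
  list(alpha = alpha, T = T, fit_low = fit_low, fit_high = fit_high)
}

# Hurwitz-free zeta(a) by direct sum plus integral tail; a > 1
.zeta <- function(a, m = 1e5) {
  v <- seq_len(m)
  sum(v^(-a)) + m^(1 - a) / (a - 1)
}

#' Power-law normalization of CTSS counts
#'
#' Fits a line to log(reverse-cumulative number of positions with >= c tags)
#' against log(c) over the distinct raw counts inside the fit range, then
#' maps every raw count monotonically onto the referent law with slope
#' -alpha and total T: a position whose count has fitted reverse-cumulative
#' rank r is assigned the value the referent law puts at rank r. Output is
#' on the TPM scale (referent total 1e6) and preserves the rank order of
#' the raw counts.
#'
#' @param counts raw per-position tag counts (one library).
#' @param params [powerlaw_params()].
#' @return numeric vector of normalized values, same order as `counts`.
#' @export
powerlaw_normalize <- function(counts, params = powerlaw_params()) {
  vals <- sort(unique(counts[counts >= params$fit_low &
                               counts <= params$fit_high]))
  if (length(vals) < 2)
    stop("need at least 2 distinct counts inside the fit range")
  revcum <- vapply(vals, function(v) sum(counts >= v), numeric(1))
  fit <- stats::lm(log(revcum) ~ log(vals))
  alpha_fit <- -unname(stats::coef(fit)[2])
  lambda_fit <- exp(unname(stats::coef(fit)[1]))
  lambda_ref <- params$T / .zeta(params$alpha)
  # equate fitted revcum lambda_fit * v^-alpha_fit with referent
  # lambda_ref * v'^-alpha_ref  =>  v' below
  (lambda_fit / lambda_ref)^(1 / params$alpha) *
    counts^(alpha_fit / params$alpha)
}

#' Distance-based clustering of CTSS positions
#'
#' Consecutive tagged positions on the same chromosome and strand join one
#' cluster while the gap to the previous position is <= maxdist; clustering
#' is independent per strand.
#'
#' @param ctss data.table with chrom, pos, strand and a count column.
#' @param maxdist maximum merging distance in bp (default 30).
#' @param count_col name of the count column.
#' @return list of tag clusters; each is a list(chrom, strand, positions,
#'   counts, tpm) sorted by position.
#' @export
cluster_ctss <- function(ctss, maxdist = 30, count_col = "count") {
  dt <- data.table::as.data.table(ctss)
  dt <- dt[dt[[count_col]] > 0]
  if (nrow(dt) == 0) return(list())
  data.table::setorder(dt, chrom, strand, pos)
  dt[, gap := pos - data.table::shift(pos), by = .(chrom, strand)]
  dt[, cl := cumsum(is.na(gap) | gap > maxdist)]
  out <- lapply(split(dt, by = "cl", sorted = TRUE), function(g)
    list(chrom = g$chrom[1], strand = g$strand[1], positions = g$pos,
         counts = g[[count_col]], tpm = sum(g[[count_col]])))
  unname(out)
}

#' Interquantile boundaries of a tag cluster
#'
#' q_low_pos is the smallest position whose cumulative count reaches
#' q_low * total; q_high_pos the smallest reaching q_high * total. Width is
#' inclusive: q_high_pos - q_low_pos + 1.
#'
#' @param cluster tag cluster from [cluster_ctss()].
#' @param q_low,q_high cumulative quantiles (defaults 0.1 and 0.9).
#' @return the cluster with q_low_pos, q_high_pos and interquantile_width
#'   fields added.
#' @export
interquantile_boundaries <- function(cluster, q_low = 0.1, q_high = 0.9) {
  if (length(cluster$positions) == 0) stop("empty cluster")
  cum <- cumsum(cluster$counts)
  total <- cum[length(cum)]
  cluster$q_low_pos <- cluster$positions[which(cum >= q_low * total)[1]]
  cluster$q_high_pos <- cluster$positions[which(cum >= q_high * total)[1]]
  cluster$interquantile_width <- cluster$q_high_pos - cluster$q_low_pos + 1L
  cluster
}

#' Aggregate replicate tag clusters into consensus clusters
#'
#' Groups of same-strand replicate clusters whose spans lie within `maxdist`
#' of each other merge into one consensus cluster; groups in which no
#' constituent reaches `tpm_min` are dropped. The consensus span is the
#' union of the constituents' interquantile (central) regions; cumulative
#' distributions, quantile positions and the dominant TSS (argmax of the
#' per-position signal summed across replicates; ties resolve to the
#' 5'-most position) are recomputed on the summed signal.
#'
#' @param replicate_clusters list (one entry per replicate) of lists of tag
#'   clusters with interquantile boundaries computed.
#' @param tpm_min minimum TPM required in at least one replicate (0.5).
#' @param maxdist maximum inter-cluster distance for merging (100).
#' @param q_low,q_high quantiles for the recomputed boundaries.
#' @return data.table of consensus clusters (cluster_id, chrom, strand,
#'   start, end, q_low_pos, q_high_pos, interquantile_width, dominant_tss,
#'   tpm, n_tss, gene_id = NA).
#' @export
aggregate_clusters <- function(replicate_clusters, tpm_min = 0.5,
                               maxdist = 100, q_low = 0.1, q_high = 0.9) {
  flat <- unlist(replicate_clusters, recursive = FALSE)
  if (length(flat) == 0) return(data.table::data.table())
  meta <- data.table::data.table(
    idx = seq_along(flat),
    chrom = vapply(flat, `[[`, character(1), "chrom"),
    strand = vapply(flat, `[[`, character(1), "strand"),
    start = vapply(flat, function(x) min(x$positions), numeric(1)),
    end = vapply(flat, function(x) max(x$positions), numeric(1)),
    tpm = vapply(flat, `[[`, numeric(1), "tpm"))
  data.table::setorder(meta, chrom, strand, start)
  meta[, gap := start - cummax(data.table::shift(end, fill = -Inf)),
       by = .(chrom, strand)]
  meta[, grp := cumsum(is.na(gap) | gap > maxdist)]
  rows <- lapply(split(meta, by = "grp", sorted = TRUE), function(g) {
    if (max(g$tpm) < tpm_min) return(NULL)
    members <- flat[g$idx]
    # summed per-position signal across constituents
    sig <- data.table::rbindlist(lapply(members, function(m)
      data.table::data.table(pos = m$positions, count = m$counts)))
    sig <- sig[, .(count = sum(count)), by = pos][order(pos)]
    span_lo <- min(vapply(members, `[[`, numeric(1), "q_low_pos"))
    span_hi <- max(vapply(members, `[[`, numeric(1), "q_high_pos"))
    inside <- sig[pos >= span_lo & pos <= span_hi]
    if (nrow(inside) == 0) inside <- sig
    cum <- cumsum(inside$count)
    total <- cum[length(cum)]
    ql <- inside$pos[which(cum >= q_low * total)[1]]
    qh <- inside$pos[which(cum >= q_high * total)[1]]
    mx <- inside$count == max(inside$count)
    dom <- if (g$strand[1] == "+") min(inside$pos[mx]) else max(inside$pos[mx])
    data.table::data.table(
      chrom = g$chrom[1], strand = g$strand[1],
      start = span_lo, end = span_hi,
      q_low_pos = ql, q_high_pos = qh,
      interquantile_width = as.integer(qh - ql + 1),
      dominant_tss = dom, tpm = total, n_tss = nrow(inside))
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0) return(out)
  data.table::setorder(out, chrom, strand, start)
  out[, cluster_id := sprintf("cc_%04d", .I)]
  out[, gene_id := NA_character_]
  data.table::setcolorder(out, "cluster_id")
  out[]
}

#' Assign consensus clusters to annotated genes
#'
#' Nearest annotated TSS within `max_dist` bp on the same strand and
#' chromosome, measured from the dominant TSS.
#'
#' @param clusters consensus cluster table.
#' @param tss_annotation data.table (chrom, pos, name, strand); pos is the
#'   0-based annotated TSS, compared against 1-based dominant positions
#'   after conversion.
#' @param max_dist assignment radius (500 bp).
#' @return the cluster table with gene_id filled where a gene is in range.
#' @export
assign_genes <- function(clusters, tss_annotation, max_dist = 500) {
  ann <- data.table::as.data.table(tss_annotation)
  out <- data.table::copy(clusters)
  for (i in seq_len(nrow(out))) {
    cand <- ann[chrom == out$chrom[i] & strand == out$strand[i]]
    if (nrow(cand) == 0) next
    d <- abs((cand$pos + 1L) - out$dominant_tss[i])
    j <- which.min(d)
    if (d[j] <= max_dist) out$gene_id[i] <- cand$name[j]
  }
  out
}

#' Select narrow (focused) promoters
#'
#' Keeps consensus clusters with interquantile width < `width_max`;
#' single-TSS clusters additionally need tpm >= `single_tss_tpm_min`; when
#' several clusters map to one gene only the highest-TPM cluster survives.
#'
#' @param clusters consensus cluster table (gene_id may be NA).
#' @param width_max exclusive width threshold (11).
#' @param single_tss_tpm_min TPM floor for single-TSS clusters (3).
#' @return filtered cluster table.
#' @export
select_narrow_promoters <- function(clusters, width_max = 11,
                                    single_tss_tpm_min = 3) {
  out <- clusters[interquantile_width < width_max]
  out <- out[!(n_tss == 1 & tpm < single_tss_tpm_min)]
  with_gene <- out[!is.na(gene_id)]
  if (nrow(with_gene) > 0) {
    keep <- with_gene[order(-tpm), .SD[1], by = gene_id]
    out <- data.table::rbindlist(list(out[is.na(gene_id)], keep),
                                 use.names = TRUE)
  }
  data.table::setorder(out, chrom, strand, start)
  out[]
}

#' Run the CAGE annotation pipeline on a replicated CTSS table
#'
#' Per replicate: power-law normalize, cluster at `maxdist_cluster`, compute
#' interquantile boundaries; then aggregate across replicates, optionally
#' assign genes, and select narrow promoters.
#'
#' @param ctss data.table with chrom, pos, strand, count_rep1..N.
#' @param params [powerlaw_params()].
#' @param tss_annotation optional gene TSS table for [assign_genes()].
#' @param maxdist_cluster,maxdist_merge distclu and consensus merge
#'   distances (30 and 100 bp).
#' @param tpm_min,width_max,single_tss_tpm_min filter thresholds.
#' @param normalize logical; set FALSE to treat raw counts as TPM (tiny
#'   fixtures without a fittable count distribution).
#' @return list(consensus = all consensus clusters, narrow = narrow subset).
#' @export
cage_pipeline <- function(ctss, params = powerlaw_params(),
                          tss_annotation = NULL,
                          maxdist_cluster = 30, maxdist_merge = 100,
                          tpm_min = 0.5, width_max = 11,
                          single_tss_tpm_min = 3, normalize = TRUE) {
  rep_cols <- grep("^count_rep", names(ctss), value = TRUE)
  if (length(rep_cols) == 0) rep_cols <- "count"
  rep_clusters <- lapply(rep_cols, function(cn) {
    dt <- ctss[, .(chrom, pos, strand, count = get(cn))][count > 0]
    if (normalize) dt[, count := powerlaw_normalize(count, params)]
    lapply(cluster_ctss(dt, maxdist = maxdist_cluster),
           interquantile_boundaries)
  })
  consensus <- aggregate_clusters(rep_clusters, tpm_min = tpm_min,
                                  maxdist = maxdist_merge)
  if (!is.null(tss_annotation) && nrow(consensus) > 0)
    consensus <- assign_genes(consensus, tss_annotation)
  narrow <- select_narrow_promoters(consensus, width_max = width_max,
                                    single_tss_tpm_min = single_tss_tpm_min)
  list(consensus = consensus, narrow = narrow)
}
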