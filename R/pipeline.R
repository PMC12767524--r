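# End-to-end orchestration of the synthetic study: generate promoters,
# simulate footprints / CAGE / a pausing time course, then run every
# analysis stage and write plain-text outputs. All randomness flows from
# the single seed in the configuration, so rerunning with the same
# configuration is byte-identical.

#' Run the full synthetic footprint study
#'
#' Stages: simulate (sequences, footprints, CAGE, time course), classify
#' (element scans + promoter typing), tss (CAGE annotation), footprints
#' (average profiles + contact midpoints), cluster (TBP shape k-means +
#' element enrichment), occupancy (CAGE-normalized occupancy, rank-sum
#' tests, binding correlation), pausing (half-life fits + quintiles).
#'
#' @param config `synthetic_config`.
#' @param outdir output directory (created if needed); NULL skips all file
#'   output and returns results in memory only.
#' @param timepoints minutes for the pausing time course.
#' @param tbp_peak_sd named list class -> TBP peak sd, giving the four
#'   class-specific profile archetypes (sharp TATA, sharp-downstream DPR,
#'   initiator-proximal TCT, diffuse HK).
#' @return named list with every stage's tables.
#' @export
run_synthetic_study <- function(config = synthetic_config(),
                                outdir = NULL,
                                timepoints = c(0, 5, 10, 20, 40),
                                tbp_peak_sd = list(TATA = 2, DPR = 2,
                                                   TCT = 5, HK = 15)) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(x, f) {
    if (!is.null(outdir))
      data.table::fwrite(x, file.path(outdir, f), sep = "\t")
    x
  }

  ## -- simulate ----------------------------------------------------------
  gen <- generate_promoter_sequences(config)
  cov_tbp <- simulate_stranded_footprints(gen$truth, config, "TBP",
                                          peak_sd = tbp_peak_sd)
  cov_tfiid <- simulate_stranded_footprints(gen$truth, config, "TFIID")
  ctss <- simulate_cage(gen$truth, config)
  tc <- simulate_pausing_timecourse(gen$truth, timepoints, config,
                                    noise = "poisson")
  if (!is.null(outdir)) {
    write_fasta(gen$seqs, file.path(outdir, "promoters.fa"))
    write_tss_bed(gen$tss, file.path(outdir, "promoters_tss.bed"))
    write_truth(gen$truth, file.path(outdir, "planted_truth.tsv"))
    write_bedgraph_pair(cov_tbp, file.path(outdir, "tbp"))
    write_bedgraph_pair(cov_tfiid, file.path(outdir, "tfiid"))
    write_ctss(ctss, file.path(outdir, "cage_ctss.tsv"))
  }

  ## -- classify ----------------------------------------------------------
  sense <- promoter_sense_sequences(gen$seqs, gen$truth)
  classes <- classify_promoters(sense)
  classes <- merge(classes,
                   gen$truth[, .(promoter_id, planted_class = class_label)],
                   by = "promoter_id")
  emit(classes, "promoter_classes.tsv")

  ## -- tss ---------------------------------------------------------------
  cage <- cage_pipeline(ctss, tss_annotation = gen$tss)
  emit(cage$consensus, "consensus_clusters.tsv")
  emit(cage$narrow, "narrow_promoters.tsv")

  ## -- footprints --------------------------------------------------------
  pm_tfiid <- extract_profile_matrix(cov_tfiid, gen$tss, w = 50)
  contacts <- detect_footprint_midpoints(average_profile(pm_tfiid, "TFIID"))
  contacts[, factor := "TFIID"]
  emit(contacts, "footprint_contacts.tsv")

  ## -- cluster -----------------------------------------------------------
  pm_tbp <- extract_profile_matrix(cov_tbp, gen$tss, w = 50)
  top <- select_top_signal(pm_tbp)
  win <- which(top$offsets >= -40 & top$offsets <= 40)
  feats <- cbind(top$sense_pos[, win, drop = FALSE],
                 top$sense_neg[, win, drop = FALSE])
  rownames(feats) <- top$promoter_ids
  km <- kmeans_profiles(rank_transform(feats), k = 4, seed = config$seed)
  specs0 <- element_specs(enrichment_mode = TRUE)
  presence <- t(vapply(top$promoter_ids, function(id) {
    hits <- scan_all_elements(sense[[id]], specs0)
    specs0$name %in% hits$element
  }, logical(nrow(specs0))))
  colnames(presence) <- specs0$name
  enr <- element_enrichment(km$assignments, presence)
  emit(km$assignments, "tbp_cluster_assignments.tsv")
  emit(enr, "element_enrichment.tsv")

  ## -- occupancy ---------------------------------------------------------
  cage_score <- stats::setNames(gen$truth$cage_expression,
                                gen$truth$promoter_id)
  occ <- cage_normalize(pm_tfiid, cage_score, mode = "occupancy")
  occ <- merge(occ, gen$truth[, .(promoter_id, class_label)],
               by = "promoter_id")
  tests <- compare_types(occ$normalized, occ$class_label)
  sig_tab <- cbind(
    TBP = rowSums(pm_tbp$sense_pos) + rowSums(pm_tbp$sense_neg),
    TFIID = rowSums(pm_tfiid$sense_pos) + rowSums(pm_tfiid$sense_neg))
  rownames(sig_tab) <- pm_tbp$promoter_ids
  bc <- binding_correlation(sig_tab)
  emit(occ, "normalized_occupancy.tsv")
  emit(tests, "occupancy_tests.tsv")
  if (!is.null(outdir))
    writeLines(bc$newick, file.path(outdir, "binding_dendrogram.nwk"))

  ## -- pausing -----------------------------------------------------------
  pause_pos <- stats::setNames(
    vapply(gen$truth$contacts, function(x) x$polii[1], numeric(1)),
    gen$truth$promoter_id)
  sig <- pause_window_signal(tc, gen$tss, pause_pos)
  hl <- assign_quintiles(fit_half_lives(sig))
  hl <- merge(hl, gen$truth[, .(promoter_id,
                                half_life_true = half_life_min)],
              by = "promoter_id")[order(half_life_min, promoter_id)]
  emit(hl, "half_lives.tsv")

  list(truth = gen$truth, tss = gen$tss, sense = sense,
       classes = classes, cage = cage, contacts = contacts,
       clusters = km, enrichment = enr, occupancy = occ,
       occupancy_tests = tests, correlation = bc, half_lives = hl)
}
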