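#!/usr/bin/env Rscript
# Stage 8: paused Pol II kinetics. Selects promoters with a paused
# footprint (average signal > 20, strand-maximum distance < 80 bp, pause
# position < +80), measures a 51 bp window on the pause position across a
# 0-40 min time course, fits s(t) = s0 * 2^(-t/h) per promoter (floored
# at 60 min) and bins the half-lives into quintiles.

source("analysis/00_config.R")

cfg <- study_config()
gen <- generate_promoter_sequences(cfg, scrubbed = TRUE)
tss <- read_tss_bed(file.path(SIM_DIR, "promoters_tss.bed"))

polii <- read_bedgraph_pair(file.path(SIM_DIR, "polii"))
pm <- extract_profile_matrix(polii, tss, w = 100)
sel <- select_paused_promoters(pm)
fwrite(sel, file.path(RESULTS, "paused_selection.tsv"), sep = "\t")
cat(sprintf("%d/%d promoters pass the pausing filters (pause at %+.0f bp median).\n",
            sum(sel$passes_filters), nrow(sel),
            median(sel[passes_filters == TRUE, pause_position])))

tc <- simulate_pausing_timecourse(gen$truth, c(0, 5, 10, 20, 40), cfg,
                                  noise = "poisson")
keep <- sel[passes_filters == TRUE, promoter_id]
pp <- setNames(sel$pause_position, sel$promoter_id)[keep]
sig <- pause_window_signal(tc, tss[name %in% keep], pp)
hl <- assign_quintiles(fit_half_lives(sig))
hl <- merge(hl, gen$truth[, .(promoter_id, half_life_true = half_life_min)],
            by = "promoter_id")
fwrite(hl[order(half_life_min, promoter_id)],
       file.path(RESULTS, "half_lives.tsv"), sep = "\t")

rel_err <- abs(hl$half_life_min - pmin(hl$half_life_true, 60)) /
  pmin(hl$half_life_true, 60)
cat(sprintf("Median half-life relative error: %.1f%%; %d/%d floored at 60 min.\n",
            100 * median(rel_err), sum(hl$floored), nrow(hl)))
cat("Quintile sizes:", paste(table(hl$quintile), collapse = ", "), "\n")
cat(sprintf("Quintile medians (min): %s\n",
            paste(sprintf("%.1f", hl[, median(half_life_min),
                                     keyby = quintile]$V1), collapse = ", ")))
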