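#!/usr/bin/env Rscript
# Stage 5: core promoter element classification. Scans every promoter for
# the ten elements in their TSS-relative windows (one mismatch for TATA,
# zero otherwise), applies the allow/forbid typing rules, compares against
# the planted classes, and builds PWMs of the upstream / initiator /
# downstream regions per class.

source("analysis/00_config.R")

cfg <- study_config()
gen <- generate_promoter_sequences(cfg, scrubbed = TRUE)
sense <- promoter_sense_sequences(gen$seqs, gen$truth)

cls <- classify_promoters(sense)
cls <- merge(cls, gen$truth[, .(promoter_id, planted_class = class_label)],
             by = "promoter_id")
fwrite(cls, file.path(RESULTS, "promoter_classes.tsv"), sep = "\t")
acc <- mean(cls$exclusive_label == cls$planted_class)
cat(sprintf("Classifier recovered the planted class for %.1f%% of %d promoters.\n",
            100 * acc, nrow(cls)))
print(table(planted = cls$planted_class, called = cls$exclusive_label))

regions <- list(upstream = -40:-20, initiator = -5:5, downstream = 20:40)
ic_rows <- list()
for (cl_name in unique(cls$planted_class)) {
  ids <- cls[planted_class == cl_name, promoter_id]
  for (rg in names(regions)) {
    pwm <- build_pwm(unname(sense[ids]), regions[[rg]])
    ic_rows[[length(ic_rows) + 1]] <- data.table(
      class = cl_name, region = rg, offset = regions[[rg]], ic = pwm$ic)
  }
}
ic_tab <- rbindlist(ic_rows)
fwrite(ic_tab, file.path(RESULTS, "region_information_content.tsv"),
       sep = "\t")
peak_ic <- ic_tab[, .(max_ic = max(ic)), by = .(class, region)]
cat("Peak information content (bits) per class and region:\n")
print(dcast(peak_ic, class ~ region, value.var = "max_ic"))
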