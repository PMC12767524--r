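#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth —
# promoter sequences (FASTA), TSSs (BED6), stranded stop-base footprints
# (bedGraph pairs), replicated CAGE tag counts (CTSS TSV) and the truth
# table every later stage is checked against.

source("analysis/00_config.R")

cfg <- study_config()
gen <- generate_promoter_sequences(cfg, scrubbed = TRUE)

write_fasta(gen$seqs, file.path(SIM_DIR, "promoters.fa"))
write_tss_bed(gen$tss, file.path(SIM_DIR, "promoters_tss.bed"))
write_truth(gen$truth, file.path(SIM_DIR, "planted_truth.tsv"))

# Pol II at paused promoters is deep by construction: the selection stage
# requires a per-position average > 20 over the 101 bp window, i.e. a few
# thousand stop bases per promoter.
for (f in c("TBP", "TFIID", "polii")) {
  cov <- simulate_stranded_footprints(
    gen$truth, cfg, f,
    peak_sd = if (f == "TBP") list(TATA = 2, DPR = 2, TCT = 5, HK = 15)
              else NULL,
    reads = if (f == "polii") 5000L else NULL)
  write_bedgraph_pair(cov, file.path(SIM_DIR, tolower(f)))
}
write_ctss(simulate_cage(gen$truth, cfg), file.path(SIM_DIR, "cage_ctss.tsv"))

cat(sprintf("Simulated %d promoters (%s), %d on the minus strand.\n",
            nrow(gen$truth),
            paste(names(table(gen$truth$class_label)),
                  table(gen$truth$class_label), collapse = ", ",
                  sep = ":"),
            sum(gen$truth$strand == "-")))
cat("Outputs in", SIM_DIR, "\n")
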