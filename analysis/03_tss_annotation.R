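#!/usr/bin/env Rscript
# Stage 3: CAGE TSS annotation. Power-law normalizes the two CTSS
# replicates, clusters tag positions (distclu-style, 30 bp), computes
# 10-90% interquantile boundaries, aggregates replicates into consensus
# clusters (100 bp, TPM >= 0.5 in at least one replicate) and selects
# narrow (focused) promoters: interquantile width < 11 bp, single-TSS
# clusters >= 3 TPM, one cluster per gene.

source("analysis/00_config.R")

ctss <- read_ctss(file.path(SIM_DIR, "cage_ctss.tsv"))
tss_ann <- read_tss_bed(file.path(SIM_DIR, "promoters_tss.bed"))

res <- cage_pipeline(ctss, tss_annotation = tss_ann)
fwrite(res$consensus, file.path(RESULTS, "consensus_clusters.tsv"),
       sep = "\t")
fwrite(res$narrow, file.path(RESULTS, "narrow_promoters.tsv"), sep = "\t")

truth <- fread(file.path(SIM_DIR, "planted_truth.tsv"))
cat(sprintf("%d consensus clusters; %d narrow (%.1f%% of %d planted).\n",
            nrow(res$consensus), nrow(res$narrow),
            100 * nrow(res$narrow) / nrow(truth), nrow(truth)))
cat(sprintf("Median interquantile width: %.0f bp; %d clusters with an\n",
            median(res$narrow$interquantile_width),
            sum(!is.na(res$narrow$gene_id))))
cat("assigned gene.\n")
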