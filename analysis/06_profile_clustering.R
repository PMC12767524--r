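#!/usr/bin/env Rscript
# Stage 6: de novo promoter typing from TBP profile shape. Keeps the top
# 90% of promoters by TBP signal in the 81 bp window, rank-transforms each
# profile, k-means clusters (k = 4, 100 starts, 30 iterations) and tests
# each cluster for core-promoter-element enrichment (Fisher + BH).

source("analysis/00_config.R")

cfg <- study_config()
gen <- generate_promoter_sequences(cfg, scrubbed = TRUE)
sense <- promoter_sense_sequences(gen$seqs, gen$truth)
tss <- read_tss_bed(file.path(SIM_DIR, "promoters_tss.bed"))

tbp <- read_bedgraph_pair(file.path(SIM_DIR, "tbp"))
pm <- select_top_signal(extract_profile_matrix(tbp, tss, w = 50))
win <- which(pm$offsets >= -40 & pm$offsets <= 40)
feats <- cbind(pm$sense_pos[, win], pm$sense_neg[, win])
rownames(feats) <- pm$promoter_ids
km <- kmeans_profiles(rank_transform(feats), k = 4, seed = cfg$seed)
fwrite(km$assignments, file.path(RESULTS, "tbp_clusters.tsv"), sep = "\t")

specs0 <- element_specs(enrichment_mode = TRUE)
presence <- t(vapply(pm$promoter_ids, function(id)
  specs0$name %in% scan_all_elements(sense[[id]], specs0)$element,
  logical(nrow(specs0))))
colnames(presence) <- specs0$name
enr <- element_enrichment(km$assignments, presence)
fwrite(enr, file.path(RESULTS, "element_enrichment.tsv"), sep = "\t")

truth_cls <- gen$truth[match(km$assignments$promoter_id, promoter_id),
                       class_label]
cat("TBP-shape clusters vs planted classes:\n")
print(table(planted = truth_cls, cluster = km$assignments$cluster))
sig <- enr[q < 0.05 & ratio > 1][order(cluster, q)]
cat(sprintf("%d (cluster, element) pairs enriched at BH q < 0.05, e.g.:\n",
            nrow(sig)))
print(head(sig[, .(cluster, element, ratio, q)], 8))
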