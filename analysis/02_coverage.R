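#!/usr/bin/env Rscript
# Stage 2: stop-base coverage handling. Demonstrates the read-level path
# (barcode deduplication, 5'-most stop base) on a small constructed read
# set, then RPM-normalizes and replicate-pools the simulated TBP coverage
# read back from its bedGraph pair.

source("analysis/00_config.R")

# read-level path: duplicates collapse, distinct barcodes do not
reads <- data.table(
  chrom = "chr2L",
  start = c(100L, 100L, 100L, 250L),
  end = c(136L, 136L, 136L, 286L),
  strand = c("+", "+", "+", "-"),
  fixed_barcode = c("CTGA", "CTGA", "TGAC", "CTGA"),
  random_barcode = c("ACGTA", "ACGTA", "ACGTA", "TTTCA"))
cov_reads <- stop_base_coverage(reads)
cat(sprintf("4 reads -> %d deduplicated stop bases (one PCR duplicate).\n",
            as.integer(cov_reads$total_signal)))

# file path: RPM + pooling of the simulated TBP "replicates"
tbp <- read_bedgraph_pair(file.path(SIM_DIR, "tbp"))
rep1 <- rpm_normalize(tbp)
rep2 <- rpm_normalize(tbp)          # identical replicate: pooling sanity
pooled <- pool_replicates(list(rep1, rep2))
write_bedgraph_pair(pooled, file.path(SIM_DIR, "tbp_pooled_rpm"))
cat(sprintf("TBP coverage: %d positions, RPM total %.0f (pooled).\n",
            nrow(pooled$cov), pooled$total_signal))
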