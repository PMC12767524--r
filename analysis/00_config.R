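# Shared configuration for the analysis drivers. Source this first.
#
# The study is run at desk scale: 50 promoters per class (200 total),
# 1000 stop bases per promoter and factor, CAGE kernel of 1 bp, 5%
# uniform background. All stages are deterministic given ROOT_SEED.

library(promnex)
library(data.table)

ROOT_SEED <- 20260925L %% 10000L
RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "synthetic")

study_config <- function(seed = ROOT_SEED) {
  synthetic_config(n_promoters_per_class = 50,
                   promoter_span = 601,
                   reads_per_factor = 1000,
                   strand_offset = 4,
                   peak_sd = 2,
                   cage_tags_per_promoter = 1000,
                   cage_kernel_sd = 1,
                   background_rate = 0.05,
                   minus_strand_frac = 0.5,
                   seed = seed)
}

dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)
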