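# promnex

Base-resolution, strand-specific analysis of ChIP-nexus/ChIP-exo
footprints at promoters.

ChIP-nexus digests crosslinked chromatin with a 5′→3′ exonuclease up to
each protein–DNA crosslink, so the 5′-most aligned base of every read
(the *stop base*) marks a contact boundary at single-base resolution. A
bound factor shows a paired footprint: a positive-strand stop-base peak
upstream and a negative-strand peak downstream of the contact. This
package implements the complete promoter-scale analysis chain around that
signal, as an R package (`R/`) driven by a numbered analysis workflow
(`analysis/`):

- **Coverage** — stop-base coverage from aligned reads with fixed+random
  barcode deduplication, RPM scaling, replicate pooling, and extraction
  of TSS-anchored profile matrices with minus-strand promoters flipped
  into sense orientation.
- **TSS annotation** — the CAGE pipeline: power-law normalization
  (α = 1.19, T = 10⁶, fit range 3–40,000), distance clustering of CTSS
  positions (30 bp), 10–90% interquantile boundaries, cross-replicate
  consensus clusters (100 bp, TPM ≥ 0.5 in ≥ 1 replicate), dominant TSS,
  and narrow-promoter selection (interquantile width < 11 bp, single-TSS
  clusters ≥ 3 TPM, one cluster per gene).
- **Footprint geometry** — average stranded profiles, contact midpoints
  m = (pos-peak + neg-peak)/2 from paired strand peaks, min–max
  normalization, and PCA (+ seeded k-means) grouping of factor profiles
  into modules.
- **Promoter typing** — IUPAC consensus scanning in TSS-relative windows
  (TATA STATAWAWR [−40,−20] with ≤ 1 mismatch; Inr, DPE, MTE, PB, DRE,
  Ohler1/6/7, TCT with 0 mismatches) and the allow/forbid rules giving
  TATA / DPR / TCT / HK labels; PWMs with per-position information
  content.
- **TBP shape clustering** — top-90% signal selection over [−40,+40],
  per-promoter rank transform, k-means (k = 4, 100 starts, 30
  iterations), and per-cluster element enrichment (two-sided Fisher
  exact, Benjamini–Hochberg).
- **Occupancy statistics** — ChIP signal normalized by CAGE expression,
  Wilcoxon rank-sum contrasts between promoter types, Pearson/Ward
  binding-correlation dendrograms, and control-vs-treated ΔPCC of
  upstream/downstream TBP against TAFs.
- **Pausing kinetics** — paused-promoter selection (average signal > 20,
  strand-maximum distance < 80 bp, pause position < +80), exponential
  half-life fits s(t) = s0·2^(−t/h) floored at 60 min, and quintile
  binning (n = 1307 → 262/261/261/261/262).
- **Synthetic data** — a generator that plants ground truth (promoter
  classes, contact positions, CAGE expression, half-lives) so every
  stage is testable without external sequencing data.

## The analysis workflow

```sh
Rscript analysis/01_simulate.R            # synthetic study data + truth
Rscript analysis/02_coverage.R            # dedup / RPM / pooling
Rscript analysis/03_tss_annotation.R      # CAGE -> narrow promoters
Rscript analysis/04_footprints.R          # contact midpoints, PCA modules
Rscript analysis/05_classify.R            # element scans, promoter types
Rscript analysis/06_profile_clustering.R  # TBP shape k-means + enrichment
Rscript analysis/07_occupancy.R           # normalized occupancy, ΔPCC
Rscript analysis/08_pausing.R             # half-lives, quintiles
```

Each driver writes its tables under `results/` and prints what it found.
On the default configuration (200 promoters, 50 per class, seed fixed in
`analysis/00_config.R`) the drivers print, among other things:

```
TFIID contact midpoints: -30, -18, 10, 19, 32
Classifier recovered the planted class for 100.0% of 200 promoters.
200 consensus clusters; 200 narrow (100.0% of 200 planted).
Median half-life relative error: 3.4%; 6/200 floored at 60 min.
```

i.e. the detector recovers the five planted contact regions exactly, the
rule-based classifier reproduces every planted promoter class, all
planted promoters survive the narrow-promoter CAGE filters at a 1 bp
initiation kernel, and half-lives fitted from the Poisson-noise time
course sit within a few percent of the planted values.

## A worked example

```r
library(promnex)

cfg <- synthetic_config(n_promoters_per_class = 10, seed = 1,
                        reads_per_factor = 2000)
gen <- generate_promoter_sequences(cfg)
cov <- simulate_stranded_footprints(gen$truth, cfg, "TFIID")
pm  <- extract_profile_matrix(cov, gen$tss, w = 50)
detect_footprint_midpoints(average_profile(pm, "TFIID"))
#>    pos_peak_offset neg_peak_offset midpoint pos_height neg_height
#> 1:             -34             -26      -30     40.725     39.500
#> 2:             -22             -14      -18     40.700     40.225
#> 3:               6              14       10     39.725     40.550
#> 4:              15              23       19     39.100     40.800
#> 5:              28              36       32     41.975     38.800
```

Five contacts were planted at −30, −18, +10, +19 and +32; each midpoint
is the mean of the paired strand-peak offsets (positive-strand peak 4 bp
upstream, negative-strand peak 4 bp downstream of the contact), and all
five are recovered exactly.

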