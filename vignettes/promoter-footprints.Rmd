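---
title: "Base-resolution promoter footprint analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-resolution promoter footprint analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promnex)
library(data.table)
```

## The problem

ChIP-nexus (a ChIP-exo variant) maps protein–DNA contacts at base
resolution: a 5′→3′ exonuclease digests crosslinked chromatin up to the
protein–DNA crosslink, so the 5′-most aligned base of each read — the
*stop base* — marks the exonuclease arrest point. A bound protein leaves a
characteristic paired footprint: a positive-strand stop-base peak just
upstream of the contact and a negative-strand peak just downstream.
`promnex` implements the full analysis chain for such data at promoters:

1. stop-base coverage from aligned reads, with barcode deduplication, RPM
   scaling and replicate pooling;
2. TSS annotation from CAGE tag counts (power-law normalization,
   distance clustering, interquantile boundaries, consensus aggregation,
   narrow-promoter selection);
3. footprint contact-midpoint detection from paired strand peaks and
   PCA-based grouping of factor profiles into modules;
4. rule-based promoter typing from core promoter elements (TATA, Inr,
   DPE, MTE, PB, DRE, Ohler 1/6/7, TCT) and PWM construction;
5. k-means clustering of per-promoter TBP profile shapes with
   core-promoter-element enrichment;
6. transcription-normalized occupancy statistics; and
7. paused Pol II half-life estimation from initiation-block time courses.

Because real promoter-scale sequencing data are large and external, the
package ships a synthetic-data generator with *planted ground truth*:
every stage can be exercised end to end against known answers.

## Coordinate and window conventions

All coordinates are 0-based half-open internally and in BED/bedGraph;
CTSS tables are 1-based, following the common CAGE convention.
TSS-relative offset 0 is the base at the dominant TSS. Wherever a
"100 bp/101 bp window centered on the TSS" is quantified, the package
uses the symmetric inclusive window [−50, +50] (101 positions); the TBP
shape-clustering window is [−40, +40] (81 positions). Minus-strand
promoters are always flipped into sense orientation before any
TSS-relative operation, with the strand planes swapped so that
"sense-positive" is the transcribed-strand-upstream footprint. The stop
base of a minus-strand read is `end − 1`, the 5′ end of the read, which
matches λ-exonuclease digestion geometry. Missing coverage positions are
zeros, never `NA`.

Barcode deduplication keys on (chrom, start, end, strand, fixed barcode,
random barcode) — the stricter reading that uses both barcodes, since
both are carried in the read names precisely to distinguish PCR
duplicates from independent ligation events.

## The synthetic-data model

The generator emulates the *study conditions*, not the sequencing
process. Each synthetic promoter occupies its own chromosome with the
TSS at the center of an odd 601 bp span; about half the promoters are
emitted on the minus strand to exercise strand flipping everywhere.

**Sequences.** Background bases are uniform over A/C/G/T. A promoter of
class TATA, DPR, TCT or HK receives a concrete expansion of its defining
IUPAC consensus planted at a uniformly drawn start offset inside the
element's window (DPR promoters receive an Inr plus one of MTE/DPE/PB;
HK promoters one of DRE/Ohler1/6/7). In *scrubbed* mode the background is
re-sampled (capped at 1,000 attempts) until no accidental occurrence of a
class-incompatible element survives — one mismatch allowed for TATA, zero
for the others, exactly mirroring the classifier — so the rule-based
classifier must recover the planted class for 100% of promoters. The cap
exists to fail loudly on over-constrained windows rather than loop
forever.

**Footprints.** Stop bases around a contact midpoint m are symmetric
Gaussians: positive-strand stops from Normal(m − strand_offset, peak_sd),
negative-strand stops from Normal(m + strand_offset, peak_sd), rounded
and clamped to the span. No generative model for footprint shape is
established in this field; symmetric Gaussians are the simplest model
with the right positive-upstream/negative-downstream geometry. The
defaults — strand_offset 4 bp, peak_sd 2 bp, 1,000 stop bases per
promoter and factor, 5% uniform background in the analysis drivers — are
placeholders in the sense that no published shape parameters exist; they
were chosen once as plausible for a well-enriched base-resolution
library. The Pol II track used by the pausing stage is simulated at
5,000 stop bases per promoter because the pausing selection targets
high-signal promoters by construction (per-position average > 20 over
101 bp requires a few thousand stop bases).

**CAGE.** Tags are multinomial around the TSS with a Gaussian kernel
(default sd 1 bp, giving interquantile widths of 3–5 bp, comfortably
below the < 11 bp focused-promoter threshold); per-promoter expression
is log-normal (median 1) scaled by 1,000 tags, with two independent
replicates.

**Pausing time course.** Expected signal at time t is
s0 · 2^(−t/h) with per-promoter half-lives log-normal around 15 min
(so that both the < 6 min and the > 45 min tails of the quintile
structure, and the 60 min flooring, are exercised). Noise is optional
Poisson.

What the generator does **not** emulate: mappability, GC bias, nucleosome
occupancy, enhancer contacts, overlapping promoters, chromatin-state
heterogeneity, or read-level artifacts. Passing tests therefore
demonstrate algorithmic correctness under the stated model, not
robustness to every property of real libraries.

## Method details and numerical choices

**Power-law normalization.** The reverse-cumulative count distribution
(number of positions with ≥ c tags) is fitted in log-log space by least
squares over the distinct counts in the range 3–40,000 and mapped
monotonically onto the referent law with slope −1.19 and total 10⁶, the
standard CAGE procedure. The referent intercept is obtained by matching
the total: λ_ref = T/ζ(α), with ζ evaluated numerically. Counts drawn
exactly from the referent law map to themselves (machine precision), and
the map preserves rank order exactly.

**Clustering and boundaries.** CTSS positions on one strand join a
cluster while the gap to the previous position is ≤ 30 bp. The
interquantile boundaries are the smallest positions whose cumulative
count reaches 10% and 90% of the cluster total; width is inclusive
(end − start + 1), so "< 11 bp" excludes an 11-position spread.
Replicate clusters within 100 bp merge into a consensus whose span is
the union of the constituents' interquantile regions; quantiles and the
dominant TSS are recomputed on the summed signal, with dominant-TSS ties
resolved to the 5′-most position. The TPM ≥ 0.5 retention filter is
applied at the merge-group level (a group survives if any constituent
reaches it), before boundary refinement. Gene assignment takes the
nearest annotated same-strand TSS within 500 bp.

**Midpoint detection.** Candidate peaks are local maxima at ≥ 20% of the
strand maximum, ≥ 3 bp apart (greedy, height-ordered). Each
positive-strand peak pairs with the nearest negative-strand peak strictly
downstream within 40 bp; ties go to the higher negative peak; unpaired
peaks are reported with NA partners. Midpoints are means of the two peak
offsets and may be half-integers. These three parameters are exposed
because no published values exist; detection is translation-equivariant
and scale-invariant by construction.

**Element scanning.** The motif *start* offset must fall inside the
window (the laxer of start-in-window vs full containment; configurable
by shifting windows). TATA allows one mismatch in classification mode;
enrichment mode forces zero mismatches for all elements. The exclusive
label resolves multi-label promoters by the priority
TATA > TCT > DPR > HK; both the label set and the exclusive label are
reported.

**Shape clustering.** The top 90% of promoters by TBP signal in
[−40, +40] (ties at the cut kept) are rank-transformed per row (average
ranks on ties, divided by the number of columns) and clustered by
Euclidean k-means with k = 4, 100 random starts and an iteration cap of
30 — the cap reading of the clustering recipe's third argument. Features
are the concatenated positive- and negative-strand vectors; cluster ids
are relabeled by descending size so only the partition is meaningful.

**Statistics.** Enrichment uses the two-sided Fisher exact test on each
(cluster, element) 2×2 table with joint Benjamini–Hochberg correction;
in/out ratio is reported as +Inf when the outside fraction is zero and
NA for 0/0. Occupancy contrasts use the two-sided Wilcoxon rank-sum test
on all observations (outlier trimming is a plotting matter only).
Binding correlation uses Pearson on log2(x + 1), distance 1 − r, and
Ward's D linkage on the un-squared dissimilarity (`hclust` method
`"ward.D"`). The upstream/downstream TBP windows for condition-delta
correlations default to [−25, −10] and [+25, +40], bracketing the −18
and +32 footprint regions; both are configurable.

**Half-life fitting.** s(t) = s0 · 2^(−t/h) is fitted by
Levenberg–Marquardt least squares initialized from the log-linear closed
form; fits failing to converge fall back to the log-linear estimate with
a flag. No baseline offset term is included. Estimates above 60 min are
floored to 60 with a flag, eliminating noise-inflated values. Quintile
binning ranks ascending (ties broken by promoter id) and hands any
remainder to the outermost bins first, so 1,307 promoters split as
262/261/261/261/262.

## Problem sizes

The analysis drivers run 50 promoters per class (200 total) at 1,000
stop bases per promoter and factor; the acceptance script uses 100 per
class for classification and shape clustering, 10⁴ stop bases for
midpoint recovery, and 500 replicates for the noisy half-life study.
These sizes were chosen so the planted effects are comfortably above the
generator's noise floor while the whole study remains a desk-scale
computation.

## A small worked example

```{r example}
cfg <- synthetic_config(n_promoters_per_class = 10, seed = 1,
                        reads_per_factor = 2000)
gen <- generate_promoter_sequences(cfg)
cov <- simulate_stranded_footprints(gen$truth, cfg, "TFIID")
pm <- extract_profile_matrix(cov, gen$tss, w = 50)
detect_footprint_midpoints(average_profile(pm, "TFIID"))
```

```{r classify}
cls <- classify_promoters(promoter_sense_sequences(gen$seqs, gen$truth))
table(planted = gen$truth$class_label, called = cls$exclusive_label)
```

## Known limitations

- The synthetic footprint model is parametric and symmetric; real
  footprints are asymmetric and factor-specific.
- Promoters live on separate synthetic chromosomes, so closely spaced or
  bidirectional promoters are never tested.
- The power-law fit assumes at least two distinct counts inside the fit
  range and errors otherwise; very shallow libraries must skip
  normalization (`normalize = FALSE` in `cage_pipeline()`).
- Half-life fitting without an offset term biases estimates when a
  stable background floor exists in real time courses.
- PCA module labels and k-means cluster ids are arbitrary; only
  partitions are contractual.
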