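---
title: "Assessing cross-species aCGH detection of gene duplicates"
author: "crosscgh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cross-species aCGH detection of gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscgh)
```

## The problem

Array comparative genomic hybridization (aCGH) compares the genomic content
of two DNA samples by competitive two-color hybridization to a probe array:
a locus duplicated in the test sample relative to the reference hybridizes
at a 2:1 ratio and shows up as a positive log2 ratio (M). When the test
sample comes from a *different species* than the one the array was designed
for, sequence divergence between the test DNA and the probes depresses
hybridization efficiency, which both pushes single-copy loci toward negative
M genome-wide and can mask true duplications entirely. `crosscgh`
provides a testbed for quantifying these biases.

The central trick is biological: hybridizing *female* test DNA against
*male* reference DNA of an X/Y system turns every X-linked feature into a
known "duplication" (two X copies versus one) and every autosomal feature
into a known negative (2:2). With thousands of X-linked probes spanning a
wide range of ortholog divergence, true and false positive rates of the
whole detection pipeline can be measured directly, per divergence level.

## The generative model

`sim_config()` + `simulate_experiment()` emulate this design. For each
feature the simulator draws:

* a sequence identity of the test-species ortholog to the platform probe
  from a truncated normal — presets `"simulans_like"` (mean 0.96, sd 0.02)
  and `"yakuba_like"` (mean 0.92, sd 0.025), truncated at 0.75 and 1, and
  `"platform"` (identity exactly 1) for the within-species control;
* a hybridization efficiency `h(id) = max(floor, 1 - beta_div * (1 - id))`.
  The linear-with-clamp form reflects the approximately linear relation
  between hybridization ratio and divergence seen in heterologous
  hybridizations. The small residual floor (`cross_hyb_floor = 0.05`)
  represents non-specific cross-hybridization: without it, strongly diverged
  loci would be perfectly dark, fail the 2-SD quality filter, and vanish
  from the divergence analysis altogether, which real diverged features do
  not do;
* an expected log ratio from the competitive-hybridization model
  `M = log2(sum copies_test * h / sum copies_ref * h)`, summing over the
  probe's target locus plus any paralogous or duplicated loci it can
  capture;
* observed per-array ratios `M + feature_effect + orientation * d(A) +
  noise`, where the probe-specific effect (SD `sigma_feature`, shared across
  arrays) models sequence-dependent bias, `d(A)` is a smooth odd cubic in
  centered log intensity representing intensity-dependent dye bias (it flips
  sign under dye swap, so loess has a real trend to remove and dye-swap
  averaging cancels it), and per-array noise has SD `sigma_array`;
* two channel intensities reconstructed from (A, M), plus additive
  backgrounds, written as a GenePix-like scan table.

Ground truth includes rare genome-difference confounders drawn
independently per feature: autosomal paralog families (present in the
platform genome, shared with the heterologous genome with probability 0.5 —
the joint divergence of paralog pairs is not empirically constrained, so
the sharing probability is an explicit knob), movement of X loci onto
autosomes and vice versa, outright deletion (which dominates the other
confounders: a deleted feature emits no heterologous hits), and
heterochromatic location, modeled as a multiplicative suppression of both
channels with independent per-channel lognormal jitter — heterochromatic
features misbehave rather than follow a specific documented mechanism. A
fabricated pair of BLAST-style tabular hit tables is emitted consistent
with all of this, so the downstream confounder classifier can be tested
end to end.

### Calibration

The defaults are calibrated, using `scripts/calibrate_simulator.R`, so that
the simulated study reproduces the qualitative anchors of the emulated
design at 18,849 features × six dye-swapped arrays: detection of X features
is about one half at 2–4% divergence and near the floor at 9–15%; sequence
identity explains roughly half (35–65%) of the variance of the normalized
mean log ratio among unconfounded single-locus features (the X copy offset
contributes to the unexplained remainder, standing in for the GC/alignment
effects of real data); the within-species control achieves ≥90% true
positives with ≤20% false positives at FDR 0.1; and a male-vs-male null
stays near the nominal FDR. This fixes `beta_div = 10.5`,
`sigma_feature = 0.2`, `sigma_array = 0.45`, `a_mean = 12`. A steeper
efficiency slope than the naive reading of "50% loss at ~2–4% divergence"
is needed because detection at 50% requires the expected ratio to sit at
the detection threshold, not at half its maximum.

### What the simulator does not emulate

Print-tip block structure, pixel-level scanning artifacts, spatial gradients,
intensity-dependent variance, nucleotide-level sequence evolution (identities
are drawn, not evolved), and correlated divergence along chromosomes. Passing
tests therefore demonstrate correctness of the pipeline's statistical
machinery and its qualitative behavior under divergence, not quantitative
transferability to any particular real platform.

## The processing pipeline

1. **Quality control** (`apply_qc`): a feature is excluded on an array
   unless each channel's foreground exceeds background by strictly more
   than two background SDs; features OK on fewer than two arrays per
   species are dropped entirely (`filter_min_arrays`).
2. **Background correction** (`background_correct_minimum`): foreground
   minus background, with non-positive values replaced by half the minimum
   positive corrected value of that array/channel.
3. **M/A computation** (`compute_ma`): dye orientation is resolved so
   positive M always means excess in the test sample.
4. **Loess normalization** (`loess_normalize`): per array, a degree-1
   robust loess of M on A (span 0.4, symmetric family, three robustifying
   iterations — common two-color defaults, exposed as arguments) is fitted
   on a chosen gene set and subtracted from *all* features. The three sets
   are `all` features, the ~1000 most conserved, or the ~100 most
   conserved. Fitting on conserved genes anchors the curve at loci whose
   ratios are not depressed by divergence; whole-array fitting absorbs the
   genome-wide depression into the baseline and pushes mildly diverged
   single-copy autosomes above zero — the false-positive inflation the
   package quantifies. Outside the subset's intensity range the fitted
   curve is clamped to its boundary value rather than extrapolated.
   In simulations the conserved sets are the features of highest
   test-species identity (ties broken by a seeded random permutation so the
   within-species control gets a genome-wide set); real conserved-gene
   lists can be supplied through the annotation table instead.
5. **Detection** (`fit_genomic_excess`): per feature, a one-sample mean of
   the orientation-resolved normalized ratios (dye swap makes this
   equivalent to a single-coefficient linear model), an empirical-Bayes
   variance prior estimated by moment matching of `log s2` with
   digamma/trigamma corrections (Newton inversion of the trigamma function,
   tolerance 1e-8; an infinite prior df when the empirical spread does not
   exceed the sampling variance), moderated t statistics, two-sided p with
   a positive-direction requirement at the call stage (a one-sided option
   is exposed), and Benjamini–Hochberg FDR control at 0.1.
6. **Evaluation** (`summarize_calls`, `detection_by_divergence`,
   `classify_error_confounders`): called X features are true positives;
   the false-positive rate is the autosomal fraction of all calls (a
   per-autosome rate is carried as a secondary column); detection curves
   bin X features by `100 - top-hit identity` into 1-point bins, excluding
   the 0–1% bin; erroneous calls are attributed to confounder categories
   derived from the hit tables, and "explained" totals count the *union*
   of categories, never the column sum. Percentages round half-up.

### Divergence-profile conventions

Presence/absence flags (`no_hit`, `ref_not_found`) use the stringent
top-hit threshold E < 1e-14; hit counts, the heterologous/platform
hit-count ratio, and the chromosome-class flags (`autosomal_only`,
`het_x_hit`, `tel_or_het`) use the looser counting threshold E < 1e-10,
matching the "any hit" phrasing of the underlying rules. The telomere rule
flags any hit overlapping the 25 kb window at either end of its
chromosome; heterochromatin is a per-scaffold annotation, and a
heterochromatic hit in either genome sets the flag. The top hit is chosen
by lowest E-value, ties broken by highest bit score, then lowest subject
coordinate — the tie-break is a package convention, as is strand handling
(hit coordinates are order-normalized and strand discarded; no downstream
rule needs it).

## Numerical and design notes

* The QC boundary is strict: a feature sitting exactly two SDs above
  background is flagged.
* With BH control and continuous noise, a handful of autosomal features
  will always clear any moderate FDR threshold — that is the designed
  behavior of FDR control, so "perfect separation" holds only in the
  vanishing-noise limit at stringent thresholds, which is how the
  separation property is tested.
* `gel50()` reports the true log2 ratio at which the full detection
  procedure reaches 50% power under the fitted prior, by Monte-Carlo
  simulation of signal features embedded in a null background (10% signal),
  with linear interpolation across a grid of levels. It is the package's
  operationalization of a matched-power summary; experiments with
  different replicate numbers can be equalized by comparing their
  50%-power levels.
* Problem sizes used by the shipped tests and the acceptance script —
  18,849 features × 6 arrays for study-scale runs, 10 seeds for averaged
  contrasts, 5,000 features for Monte-Carlo prior recovery — keep every
  individual run under a few seconds while leaving Monte-Carlo error well
  inside the asserted bands.
* All randomness flows from a single integer seed; identical configs
  reproduce every table byte-identically.

## Known limitations

The conserved-set membership in simulations is an identity-ranking proxy,
not a curated ortholog list. Confounder probabilities are order-of-magnitude
choices sized to echo the relative frequencies reported for real
inter-species comparisons, not fitted quantities. The empirical-Bayes model
assumes exchangeable variances; intensity-dependent variance is out of
scope. Between-array normalization is deliberately absent — the design is
within-array ratios plus replicate averaging.
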