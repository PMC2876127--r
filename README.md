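# crosscgh

Cross-species array comparative genomic hybridization (aCGH) can detect
gene duplications in species that lack their own microarray platform — but
sequence divergence between the hybridized DNA and the array probes biases
what gets found. `crosscgh` is an R package for quantifying that bias. It
implements, end to end, the assessment design in which heterologous
**female** genomic DNA is competitively hybridized against platform-species
**male** DNA, so that every X-linked feature is a known "duplication"
(2 copies vs 1, expected log2 ratio +1) and every autosomal feature a known
negative (2:2, log2 ratio 0). True and false positive rates of the whole
detection pipeline can then be measured directly, per divergence level,
without any curated duplicate list.

The package is aimed at people designing or interpreting comparative
genomic hybridization studies: it shows how detection decays with ortholog
divergence, how much a conserved-gene normalization strategy buys, and how
genome differences (paralog families, gene movement on/off the X,
deletions, heterochromatin) masquerade as false calls.

## What it computes

For each feature *g* with per-array normalized log ratios
*M<sub>g1</sub> … M<sub>gn</sub>* (dye swap resolved), the model is a
one-sample moderated *t*:

- coefficient  *b̂<sub>g</sub> = mean(M<sub>gi</sub>)*, sample variance
  *s²<sub>g</sub>*, df *n − 1*;
- empirical-Bayes prior (d₀, s₀²) estimated by moment matching of log *s²*
  (digamma/trigamma, Newton inversion of the trigamma function);
- posterior variance  *s̃²<sub>g</sub> = (d₀s₀² + df·s²<sub>g</sub>)/(d₀ + df)*,
  moderated *t<sub>g</sub> = b̂<sub>g</sub> / √(s̃²<sub>g</sub>/n)* with
  d₀ + df degrees of freedom;
- Benjamini–Hochberg FDR control; a feature is called in **genomic excess**
  when *q < 0.1* and *b̂ > 0*.

Upstream: 2-SD quality filtering, "minimum" background correction, and
within-array loess normalization of M on A fitted on a chosen gene set
(all features, ~1000 conserved, or ~100 conserved genes) and applied to
all features. Downstream: TP/FP/FN accounting over the X/autosome truth,
detection-by-divergence curves, BLAST-hit-derived confounder
classification, and a GEL50 power summary (the log2 ratio at 50%
detection power). A self-contained simulator generates scan tables, hit
tables and ground truth with calibrated divergence, noise and confounder
structure, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(crosscgh)

cfg <- run_config(sim = sim_config(species = "simulans_like", seed = 42))
out <- run_pipeline(cfg)
#> [crosscgh] simulate: 18849 features x 6 arrays (simulans_like), seed 42
#> [crosscgh] qc: 18328 of 18849 features analyzable (>= 2 ok arrays)
#> [crosscgh] normalize: set 'conserved_1000', span 0.40
#> [crosscgh] detect: 1222 of 18328 features called in excess (FDR 0.10)
#> [crosscgh] evaluate: tp 1094, fp 128, fn 1956; FN explained 11%, FP explained 46%

print(out$fit)
#> Genomic-excess fit (moderated one-sample t per feature)
#>   features analyzed : 18328
#>   variance prior    : d0 = 84.55, s0^2 = 0.20638
#>   called in excess  : 1222 at FDR 0.1 (two-sided, coef > 0)

out$summary[, c("n_x_analyzed", "tp", "fp", "fn", "tp_pct", "fp_pct")]
#>   n_x_analyzed   tp  fp   fn tp_pct fp_pct
#> 1         3050 1094 128 1956     36     10
```

Of the 3,050 analyzable X features — all of them genuinely present in
double genomic content — only 36% are recovered at FDR 0.1 in this
"simulans-like" run (~4% mean divergence), versus ~93% in the
within-species control (`species = "platform"`). The decay is strongly
divergence-dependent:

```r
head(out$divergence_curve[!out$divergence_curve$low_support, ], 5)
#>   bin_lo bin_hi   n prop_detected low_support
#> 1      1      2 322    0.87577640       FALSE
#> 2      2      3 436    0.71788991       FALSE
#> 3      3      4 556    0.42446043       FALSE
#> 4      4      5 616    0.16071429       FALSE
#> 5      5      6 456    0.04385965       FALSE
```

Detection falls from ~88% at 1–2% divergence to under 5% beyond 5% —
cross-species aCGH is biased toward recovering highly conserved
duplicates. Rerunning with `normalization_set = "all"` instead of the
conserved-gene anchor roughly quintuples the false positive rate, which
is the case for conserved-gene normalization in heterologous
hybridizations.

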