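Package: crosscgh
Title: Cross-Species Array CGH Assessment of Gene-Duplicate Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing how well two-color array comparative genomic
    hybridization (aCGH) detects gene duplicates when the hybridized sample
    comes from a species diverged from the array platform. X-linked features
    in a female-versus-male design serve as known duplications (2N vs 1N).
    The package simulates cross-species genomic hybridizations with ground
    truth, performs quality control, minimum background correction, and
    within-array loess normalization anchored on conserved-gene subsets,
    calls genomic excess with empirical-Bayes moderated t-statistics at a
    Benjamini-Hochberg false discovery rate of 0.1, and quantifies true and
    false positive rates, divergence-dependent detection decay, and
    sequence-similarity confounders derived from BLAST-style hit tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
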