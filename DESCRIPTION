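Package: microdyn
Title: Longitudinal Stability Analysis of Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the temporal stability of longitudinal
    microbiome cohorts sampled at repeated time points. Implements Taylor's
    power-law mean-variance scaling per subject (variability V and scale
    index beta, with a standardized V-beta parameter space and reference-group
    coverage regions), the rank stability index (RSI) for per-feature rank
    trajectories, consecutive-pair Jaccard stability series with within- and
    between-group testing, alpha-diversity endpoint comparisons, a permutation
    PERMANOVA on arbitrary distance matrices, before/after developmental-event
    comparisons, and a seeded synthetic cohort generator with controlled
    mean-variance scaling and taxa-to-function redundancy for end-to-end
    testing without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
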