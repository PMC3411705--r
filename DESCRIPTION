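Package: quantdiff
Title: Two-Stage Normalization and Differential Enrichment Calling for
    Histone-Modification ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially enriched (DHE) and constitutively
    highly enriched (CHE) genomic bins between two histone-modification
    ChIP-seq libraries.  Stage one removes stochastic background noise
    with an amplified-binomial null model and empirical false discovery
    rate thresholding, and removes local genomic bias by iterative
    quantile normalization of an input-DNA control with outlier removal.
    Stage two places the surviving bins of both libraries on a common
    scale via a monotone-spline inverse cumulative distribution
    transform and applies fold-change rules to label bins, merging
    adjacent calls into regions.  Includes the simpler comparator
    normalizations (unit-mean, quantile-only, rank, two-stage
    unit-mean), evaluation procedures (gene-density bias profiles,
    promoter sensitivity and error, ROC construction, replicate
    false-positive rate, promoter gene typing and sixteen-class
    bivalent-state classification), and a seeded synthetic-data
    generator with known per-bin truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
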