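Package: slopehunt
Title: Collider-Bias Correction for Conditional GWAS by Model-Based Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects collider (index-event) bias in genome-wide association
    studies of an outcome conditioned on another phenotype, such as case-only
    studies of disease prognosis or BMI-adjusted metabolic traits. The
    Slope-Hunter estimator fits a constrained two-component bivariate Gaussian
    mixture to summary statistics by expectation-maximisation, identifies the
    cluster of variants affecting only the conditioning trait, and uses its
    slope as the bias-correction factor applied to all variant-outcome
    associations. Includes summary-statistics harmonisation and LD pruning,
    the Dudbridge Hedges-Olkin regression comparator, a simulation engine for
    the four-cluster generative model of conditional GWAS, and a type-1
    error/power/bias evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
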