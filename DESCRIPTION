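Package: pestrisk
Title: Establishment Risk and Economic Impact Assessment for Invasive Crop Pests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative establishment-risk assessment of
    invasive agricultural pests: maximum-entropy habitat-suitability
    modelling with small-sample AICc tuning over regularization and
    feature-class grids, threshold-based suitability classification with
    spherical cell-area accounting and crop-mask overlay, kernel-density
    n-dimensional hypervolume comparison of climatic niches (Sorensen
    overlap, centroid distance), and a PERT/Latin-hypercube Monte Carlo
    model of potential economic losses and control benefits with
    Spearman rank sensitivity analysis. Includes a synthetic-data module
    generating correlated environmental rasters, presences from a known
    suitability surface, crop masks and multivariate-normal niche clouds
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
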