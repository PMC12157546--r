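Package: cccr
Title: Clustermatch Correlation Coefficient for Mixed-Type Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Clustermatch Correlation Coefficient (CCC), a
    clustering-based association statistic that detects linear and nonlinear
    relationships between numeric, categorical, and mixed-type feature pairs.
    Provides quantile-based partitioning, a batched Adjusted Rand Index kernel
    with a deterministic chunked backend, an all-vs-all pairwise engine over
    expression matrices, permutation-based significance testing and null
    thresholds, tiered agreement/disagreement analysis against Pearson and
    Spearman coefficients, gene-metadata correlation for interpreting
    nonlinear patterns, and seeded generators for canonical relationship
    fixtures (monotone, quadratic, sex-dimorphic, Simpson reversal, masked
    subset, null).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
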