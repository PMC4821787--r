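Package: metamargin
Title: Marginal Method of Moments for Multivariate Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint inference on correlated effect sizes from multiple
    univariate meta-analyses without requiring within-study correlations.
    Implements the marginal method of moments (MMoM), which augments
    DerSimonian-Laird univariate random-effects fits with a moment estimate
    of the covariance between the pooled estimates, enabling valid joint
    inference and delta-method inference for functions of the pooled
    effects. Also provides the bivariate random-effects comparators that do
    require within-study correlations (Jackson's multivariate method of
    moments and REML), a meta-regression extension, large-variance
    augmentation for outcomes missing completely at random, and a
    simulation framework for bias, coverage and relative-efficiency
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
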