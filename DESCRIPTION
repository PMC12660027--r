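Package: raterdpm
Title: Bayesian Nonparametric Heteroscedastic Models for Rater Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dirichlet process mixture (DPM) models for continuous and
    coarsened/ordinal rating data from crossed subject-by-rater designs.
    Fits Bayesian nonparametric (BNP), semiparametric (BSP) and parametric
    (BP) heteroscedastic rating models by truncated stick-breaking blocked
    Gibbs sampling with a derivatives-matching update for gamma shape
    parameters, applies semi-centering post-processing for identifiability,
    and computes a family of intraclass correlation (ICC) estimators
    including a certified lower bound of the expected pairwise ICC.
    Includes posterior density grids, posterior similarity matrices with
    variation-of-information point partitions, WAIC model comparison,
    posterior predictive checks, synthetic-data generators for unimodal,
    bimodal and multimodal rating scenarios, and a reduced model for
    one-way designs.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
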