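Package: famgxe
Title: Pedigree Variance Components and Continuous Gene-Environment
    Interaction for Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of nuclear-family studies:
    pedigree parsing and recursive kinship (2*Phi) computation, conversion of
    3-day activity diaries to total daily energy expenditure (TDEE),
    covariate adjustment with rank-based inverse normal transformation,
    maximum-likelihood polygenic variance-components heritability estimation,
    and a continuous genotype-by-energy-expenditure interaction model in
    which genetic and environmental variances are log-linear functions of
    TDEE and the genetic correlation decays exponentially in pairwise TDEE
    differences. Model contrasts are tested with boundary-corrected
    mixture chi-square likelihood-ratio tests. Includes a synthetic
    family-study generator (pedigrees, TDEE, diaries, traits) and a
    gene-dropping kinship oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
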