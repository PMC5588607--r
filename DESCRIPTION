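Package: rrmi
Title: Multiple Imputation Methods for Relative Risk Estimation with
    Missing Outcome and Exposure Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo evaluation of multiple imputation strategies for
    estimating adjusted relative risks from log binomial models when both the
    binary outcome and an exposure are missing at random. Implements
    fully conditional specification (chained equations with logistic and
    Bayesian linear imputation models), multivariate normal imputation by
    data augmentation with EM starting values and adaptive rounding of
    binary variables, deletion of imputed outcomes before analysis,
    complete case analysis, log binomial and modified Poisson (robust
    variance) estimators, and Rubin's-rules pooling, together with a
    simulation harness that calibrates data-generating models to target
    outcome prevalence and missingness rates and summarises bias,
    standard errors, coverage and mean square error across replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
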