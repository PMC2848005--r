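Package: corrvim
Title: Random Forest Permutation Variable Importance Under Predictor
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation machinery for studying how out-of-bag
    permutation variable-importance measures (VIMs) from regression
    random forests behave when predictors are correlated. Provides the
    block-equicorrelated Gaussian generating model, closed-form truths
    for bivariate regression slopes and marginal predictor-outcome
    correlations, Monte-Carlo bias and 95% coverage evaluation of full
    and single-predictor least-squares models, an instrumented
    CART-style regression forest (subsampling without replacement,
    per-node random candidate draws, recorded split features and
    thresholds), unconditional, scaled and conditional (within-strata)
    permutation importances, and split-variable selection-frequency
    tallies, together with study orchestration and ggplot2 summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
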