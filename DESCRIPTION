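Package: evrtest
Title: Testing Equality of Variance Ratios in Moderation Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the ratio of the standard deviations of two
    correlated variables is constant across the levels (or range) of a
    moderator, the condition under which moderation of regression slopes
    and moderation of correlations coincide. Implements the Wald test of
    the log variance-ratio contrast for categorical moderators, a
    constrained multi-group bivariate-normal maximum-likelihood engine
    with likelihood-ratio model comparisons (homogeneous variances,
    equal variance ratios, equal slopes, equal correlations), maximum
    likelihood for continuous moderators with log-link standard-deviation
    and Fisher-link correlation submodels, seeded bivariate normal and
    skew-normal samplers, and a Monte-Carlo harness for Type I error,
    power, and bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
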