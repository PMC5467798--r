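Package: crtmiss
Title: Missing Continuous Outcomes in Cluster Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the impact of baseline-covariate-dependent
    missingness on the analysis of two-arm cluster randomised trials with
    continuous outcomes. Generates trial data from a random-intercept model
    with a per-arm covariate effect and a per-arm logistic missingness
    mechanism; implements unadjusted and covariate-adjusted cluster-level
    analyses, the Donner-Klar adjusted t-test, complete-records linear mixed
    models, cluster-mean and group-mean single imputation, and random-effects
    multiple imputation with Rubin's rules and Barnard-Rubin adjusted degrees
    of freedom; evaluates the analytic bias and variance of the cluster-level
    estimators under the selection model by numerical integration; and
    provides a Monte-Carlo harness reporting bias, average estimated standard
    error and coverage over factorial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
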