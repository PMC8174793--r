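Package: propelicit
Title: Expert-Elicited Priors for Daily Response Propensity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting expert-elicited attempt-level response
    rates into pooled normal priors on logistic regression coefficients,
    fitting discrete-time response propensity models for survey contact
    attempts under maximum likelihood or Bayesian (MAP) estimation with
    expert or historical precision-weighted priors, replaying a data
    collection period day by day, and scoring daily predictions by bias
    and root mean squared error against an end-of-collection target model.
    Includes a synthetic paradata generator emulating a 12-week quarter of
    two-stage screener contact attempts and simulated expert panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
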