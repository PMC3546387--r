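Package: coxtvcsim
Title: Simulate Survival Times for Cox Models with Time-Varying Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates event times from Cox proportional-hazards models with a
    single time-varying covariate and arbitrary fixed covariates, by closed-form
    inversion of the subject-specific cumulative hazard for exponential, Weibull
    and Gompertz baseline hazards. Supports single-switch binary exposures,
    alternating (piecewise-binary) exposures, cumulative linear dose, and
    time-invariant covariates; applies administrative or random uniform
    censoring; expands subjects into counting-process (start-stop) records for
    time-varying Cox fitting; and runs Monte-Carlo power studies for
    time-varying treatments over a hazard-ratio grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
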