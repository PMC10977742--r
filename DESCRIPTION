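Package: bmidiab
Title: Multi-State Markov Modelling of Body-Mass-Index Dynamics and Type 2
    Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a ten-state continuous-time Markov model of progression and
    regression across body-mass-index (BMI) categories and onset of type 2
    diabetes to interval-censored health-survey panel data, using
    piecewise-constant transition intensities with proportional-hazards
    covariate effects for sex, age class and calendar period. Provides a
    synthetic survey-panel generator with exact stochastic simulation,
    maximum-likelihood estimation with confidence intervals, goodness-of-fit
    summaries, mortality-adjusted birth-cohort projection of population
    prevalence under public-health intervention scenarios, and lifetime risk
    of type 2 diabetes under competing mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
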