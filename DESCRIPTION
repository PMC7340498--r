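Package: snakeburden
Title: Snakebite Mortality and Burden Estimation from Verbal-Autopsy Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating national snakebite mortality and bite burden
    from verbal-autopsy style death records and small-area survey demography,
    in the style of the Indian Million Death Study analyses. Implements
    dual-coder inclusion rules with plausible-range construction, sampling
    weighted cause fractions with moving-average smoothing and demographic
    envelope scaling, age-standardized rates and cumulative risk of death
    before age 70, cubic-spline trend projection, harmonic Poisson models of
    seasonality, altitude profiles of crude death rates, Bayesian Poisson
    models of national age-sex rates and geostatistical spatially smoothed
    relative risk surfaces with population-at-risk tabulation, and indirect
    prevalence estimation from literature case-fatality regressions. A
    synthetic-data generator emulates the survey's structure end to end so
    every stage can be validated against a known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
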