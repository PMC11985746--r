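Package: mrpop
Title: Probabilistic Multiregional Population Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian log-bilinear models for the five demographic components
    of subnational population change (interregional migration, mortality,
    fertility, immigration and emigration), latent time-effect forecasting
    with autoregressive and random-walk processes, and a multiregional
    cohort-component projection engine that converts posterior draws of
    component forecasts into predictive distributions of population by
    region, age and sex.  Includes a synthetic-data generator emulating
    state-level Australian-style inputs, a log-linear model-selection
    harness, and demographic summary measures (total fertility rate, life
    expectancy at birth, predictive intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
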