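Package: heatmort
Title: Event-Based Heatwave Excess-Mortality Modelling with Thermal Comfort Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing heat-related excess mortality from daily
    maxima of thermal comfort indices. Computes perceived temperature (PT)
    from a Fanger-type predicted-mean-vote heat balance, wet-bulb globe
    temperature (WBGT) from an empirical Korean polynomial with Stull's
    wet-bulb approximation, extracts heatwave events (runs of days above a
    threshold), relates log-scale event magnitudes to event-mean mortality
    rates by ordinary least squares with a threshold/lag grid search, and
    evaluates fitted models by RMSE/NRMSE on chronological train/test
    splits. Includes a synthetic weather and Poisson mortality generator
    for end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
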