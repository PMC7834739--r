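Package: zooptrends
Title: Zooplankton Biomass Anomalies, Dynamic Factor Analysis and Salmon
    Survival Models for the Strait of Georgia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting irregular net-tow zooplankton records into
    seasonal and annual log10 biomass anomalies (ICES method, with zero
    replacement and a climatological base period), deriving normalized annual
    anomalies of physical ocean drivers (wind stress, river peak-flow timing,
    lighthouse temperature and salinity, climate indices), extracting shared
    latent trends by dynamic factor analysis (EM with an exact Kalman
    filter/smoother, structured observation variance, AICc model selection and
    varimax rotation), locating regime boundaries by chronologically
    constrained incremental sum-of-squares clustering with a broken-stick
    randomization test, and relating salmon marine survival to zooplankton and
    physical covariates through a staged regression protocol (KPSS
    stationarity screening, exhaustive best-subsets search, regression with
    ARMA errors selected by AICc, repeated k-fold cross-validation and
    prediction intervals on the survival scale). Includes a synthetic-data
    generator that emulates the uneven sampling effort, lognormal sample
    noise, latent-trend covariance and survival-generating process of a
    multi-decadal coastal monitoring program, so the whole pipeline can be
    exercised end to end without access to the monitoring database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
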