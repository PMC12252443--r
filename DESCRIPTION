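Package: fermentforge
Title: Fuzzy Simulation, Soft Sensing and Recurrent Forecasting of Wine Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring and forecasting yeast alcoholic fermentation
    of wine. Provides oenological and gas-phase unit conversions (Baume/Brix/
    specific gravity, Henry's-law CO2 partitioning, ethanol ppm and percent
    alcohol by volume), a fuzzy phase-blended simulator of multivariate
    fermentation time series (biomass, sugar, CO2, pH, temperature, alcohol), a
    data-calibrated Mamdani fuzzy soft sensor that infers alcohol concentration
    from the other fermentation variables, and a variable-depth stacked LSTM
    sequence-to-sequence forecaster with two-stage architecture auto-tuning and
    chunked continual training, implemented in compiled code. Includes CSV and
    JSON telemetry input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
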