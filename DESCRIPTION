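Package: mitovo2
Title: Automated Mitochondrial Oxygen Consumption Analysis from MitoPO2 Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of mitochondrial oxygen consumption (mitoVO2)
    from 1-Hz mitochondrial oxygen tension (mitoPO2) time series recorded
    during stop-flow measurements with skin-based protoporphyrin IX
    oximetry. Detects measurement start points with a bidirectional LSTM
    sequence labeler, cleans the per-sample labels with a deterministic
    rule engine, and estimates the maximal oxygen consumption (Vmax) of
    each stop-flow decay by nonlinear least-squares fitting of a modified
    Michaelis-Menten oxygen disappearance model that accounts for diffusive
    oxygen influx. Includes a synthetic cohort generator for end-to-end
    testing, start-point matching accuracies, and Bland-Altman agreement
    statistics with extended limits of agreement for repeated measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
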