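Package: infodemsim
Title: Equation-Based and Agent-Based Simulators for Infodemic Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time SEIRS-class compartmental models and NetLogo-style
    agent-based simulators for the spread of misinformation through a
    population. Includes a simple agent-based model that emulates the
    compartmental state machine through point-to-point contact on a toroidal
    grid, an enhanced model with an explicit information environment
    (stigmergic posting and consumption of true and false content, energy
    budgets, and homophily-gated transmission), intermodel-equivalence
    metrics (Pearson correlation and normalized root-mean-square error with a
    zero-variance adjustment rule), a full-grid sweep harness, and a
    multi-objective calibration procedure for fitting either model family to
    longitudinal acceptance time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
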