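Package: emsim
Title: Empirical Simulation and Bootstrap for Multistate Event Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and resampling of multistate event-history data from a
    multivariate cumulative-hazard measure, either parametric or purely
    empirical (Nelson-Aalen increments), following the hazard-based nested
    competing-risks construction of Gill and Johansen.  Includes nonparametric
    estimation (Nelson-Aalen increments, the Aalen-Johansen transition
    probability estimator, state-occupation probabilities, Aalen-type
    covariance recursion, log-log transformed confidence intervals, reverse
    Kaplan-Meier censoring distributions), an illness-death joint model for a
    dichotomous internal time-dependent exposure, and a bootstrap for
    transition and state-occupation probabilities that needs only published
    cumulative-hazard information rather than individual patient data,
    together with nested coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
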