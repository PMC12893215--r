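Package: musicphys
Title: Change-Point-Driven Analysis of Music-Physiology Coupling
Version: 0.1.0
Authors@R:
    person("HeartBeat", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking expressive musical events to cardiovascular and
    respiratory dynamics. Implements an ensemble change-point detection
    framework (PELT and binary segmentation with Gaussian mean-shift and
    empirical-distribution costs), time-varying heart-rate-variability
    spectral analysis with a respiration-guided high-frequency band,
    Gaussian-kernel event-density representations, canonical correlation
    analysis with surrogate- and permutation-based variate selection,
    change-point connectivity graphs, event-locked pre/post response testing
    with Bonferroni control, baseline autonomic stratification via PNS/SNS
    composite indices and k-means clustering, and generalized-additive-model
    analysis of individual response similarity. Includes a fully
    parameterized synthetic-cohort generator with planted ground truth so
    the entire pipeline is testable without access to raw study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
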