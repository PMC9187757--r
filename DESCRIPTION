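Package: trackpop
Title: Classification-Based Motion Analysis of Single-Particle Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-based motion analysis of single-particle
    tracking data. Trajectories imported from localization/tracking tables are
    described by per-track scalar properties (path length, tortuosity,
    gyration-tensor elongation, spatial entropy, minimum-bounding-circle
    statistics), classified into motion-behaviour populations with hierarchical
    threshold trees (manual or trained by greedy Gini induction), and quantified
    per population with time-averaged and time-ensemble-averaged mean squared
    displacement analysis including localization-error and motion-blur
    corrections, and with survival-function analysis of squared displacements
    fitted by exponential mixtures. A two-state transient-trapping simulator
    with focal-slice visibility and defocus-dependent localization error
    generates realistic synthetic data sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
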