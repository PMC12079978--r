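Package: rutmove
Title: Moving-Window Movement and Activity Analysis for Breeding-Season Deer Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A treatment/control biologging analysis pipeline for GPS-collared
    white-tailed deer: exact simulation of range-resident Ornstein-Uhlenbeck and
    OU-foraging movement with seasonal breeding dynamics, moving-window (7-day
    size, 3-day slide) continuous-time movement-model fitting with AICc
    selection, autocorrelated kernel density home-range areas, diffusion and
    mean daily distance, utilization-distribution quantile excursivity,
    VeDBA-based accelerometer activity states with per-collar threshold
    detection, hierarchical generalized additive location-scale trend models
    with credible bands, and Fisher's exact mortality comparison. A synthetic
    cohort generator reproduces the statistical structure of the study design
    so every stage is testable without the restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
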