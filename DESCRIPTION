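Package: gazekit
Title: Analysis Pipeline for Webcam-Based Eye-Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing webcam-based (and lab-based) eye-tracking
    experiments built around screen areas of interest (AOIs): post-hoc
    midline/AOI bias correction estimated from per-trial fixation periods,
    preregistered participant/trial/sample exclusion cascades with auditable
    reports, paradigm analyses for the gaze cascade effect, the novelty
    preference, and the visual world paradigm (viewing proportions and
    time-courses), and an inferential layer with one-sided t tests, Cohen's d
    with one-sided noncentral-t confidence bounds, JZS Bayes factors under a
    Cauchy prior, exact binomial tests, a priori power solvers, and Bayesian
    sequential stopping rules. Includes a synthetic gaze-data generator that
    emulates webcam-grade measurement noise, per-trial spatial bias, and
    irregular sampling with known ground truth, so the full pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
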