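Package: gaitview
Title: Segmentation, Classification and Graphical Scoring of Lower-Back IMU Gait Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns a six-channel lower-back inertial measurement unit (IMU)
    recording from a semi-free-living gait protocol into a segmented, labeled
    and scored account of the subject's walking. Recordings are bandpass
    filtered, projected into a 28-bin short-time Fourier representation, and
    segmented with an exact penalized change-point solver (PELT) whose penalty
    is calibrated from expert annotations. Segmented regimes are classified
    with a cascade of linear support-vector machines (walking versus
    non-walking, then sedentary versus non-sedentary), walking regimes are
    scored on four gait criteria (stability, sturdiness, symmetry, steadiness)
    built from RMS ratios and the unbiased autocorrelation of craniocaudal
    acceleration, and scores are compared to a healthy reference model and
    rendered as an annular summary chart. A synthetic-protocol generator with
    controllable gait-quality knobs makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
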