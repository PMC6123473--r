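Package: errpkey
Title: Hybrid EEG and Eye-Gaze Error Detection for Gaze-Based Keyboards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an error-detection system for
    dwell-time gaze keyboards from synchronized EEG and eye-tracking streams.
    Provides event-locked epoching around key registrations, labelling of
    typed-versus-intended character streams, Discriminant Spatial Pattern
    (DSP) spatial filtering of error-related potentials, Hjorth descriptors
    of the accumulated gaze-distance series, SMOTE class balancing, linear
    support-vector-machine classifiers with unimodal, early-fusion and
    late-fusion decision schemes and a movable decision threshold,
    utility-gain threshold tuning, Monte-Carlo and leave-one-sentence-out
    cross-validation, and typing-time gain estimation. A seeded synthetic
    typing-session generator emulates the assumed statistical structure of
    such recordings so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
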