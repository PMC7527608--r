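Package: antisaccade
Title: Pro- and Anti-Saccade Assessment with Velocity-Threshold Saccade
    Detection and Eye-Tracker Timing Diagnostics
Version: 0.1.0
Authors@R:
    person("Motor Control", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for standardized pro- and anti-saccade assessment with
    head-mounted binocular eye trackers sampling at 120 Hz. Generates the
    standardized session protocol (practice, task phases, side balance,
    fore-period law), reads and writes per-frame eye-sample logs with
    per-field validity bitmasks, converts normalized gaze-direction
    vectors to visual angle, despikes traces with a running median,
    detects saccades with a five-case normalized-velocity-threshold
    classifier yielding latency, signed peak velocity, direction errors
    and reflexive responses, summarises pupillometry, and diagnoses
    eye-tracker sampling-interval behaviour (warm-up stabilization,
    duplicate frames, interval classes). A seeded gaze-trace simulator
    with main-sequence kinematics exercises the whole pipeline without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
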