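Package: gripswitch
Title: Switched Feedforward Grip-Force Control in Elastic Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of grip-force control during vertical
    reaching movements into one-sided elastic force fields of graded
    stiffness. Provides a synthetic-cohort generator (minimum-jerk
    kinematics, haptic spring rendering with C1 onset smoothing, a switched
    feedforward grip controller with hysteretic stiffness thresholds and
    catch trials), the signal-processing chain (central differences,
    zero-phase 20 Hz low-pass filtering, movement-onset and impact
    detection, per-trial feature extraction), and the switching-detection
    statistics: fourth-order polynomial extremum localization of grip-force
    peaks versus log stiffness, hinge (piecewise-linear) regression with
    AIC model comparison, participant-level bootstrap confidence intervals,
    binned sustained-divergence testing of real versus catch accelerations,
    and acceleration-sign threshold estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
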