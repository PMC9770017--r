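Package: quadgait
Title: Quadrupedal Gait Perturbation Analysis for Treadmill Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phase-dependent cutaneous reflex
    experiments during quadrupedal treadmill locomotion. Detects stance
    onsets and offsets from toe marker trajectories, assembles per-limb gait
    cycles, classifies stimuli into four step-cycle phases, extracts
    control/stimulated/post cycle triads for all four limbs, and computes
    spatiotemporal metrics (support-period decomposition, step and stride
    lengths, joint angles, marker heights) and EMG burst metrics (band-pass
    filtering, envelope, double-threshold burst detection, normalized mean
    amplitude). Group effects are summarized per phase with Friedman
    repeated-measures tests and Bonferroni-adjusted Wilcoxon post hoc
    comparisons. A synthetic-session generator produces footfall schedules,
    forward-kinematic marker trajectories, EMG and stimulus trains with
    injected phase-specific perturbation effects for validation and power
    analysis.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
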