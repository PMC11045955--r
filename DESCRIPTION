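Package: gaitdtw
Title: Swing-Phase Locomotion-Mode Recognition by Multidimensional
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-matching recognition of locomotion modes and mode
    transitions (level walking, walking-to-stair-ascent,
    walking-to-stair-descent) from wearable gait sensors. Continuous
    multichannel recordings (IMU accelerometer/gyroscope axes, joint and
    segment angles, in-shoe plantar pressure) are low-pass filtered,
    normalized, and segmented into gait cycles anchored at toe-off so that
    the swing phase comes first. Per-subject, per-mode reference templates
    are built by resampling cycles to the average length and averaging
    sample by sample; an unknown (possibly partial) cycle is classified by
    multidimensional dynamic time warping distance to each subject's
    template set, with majority voting across subjects and an
    average-distance tie break. Includes prefix-of-cycle (early
    recognition) operation, minority-class augmentation (amplitude
    scaling, resampling, additive white Gaussian noise at fixed SNR),
    greedy forward channel selection, leave-one-subject-out evaluation,
    and a synthetic multi-subject gait generator with analytic ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
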