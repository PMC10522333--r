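Package: usvloc
Title: Hybrid Localization and Assignment of Mouse Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes rodent ultrasonic vocalizations (USVs) recorded with a
    64-channel planar microphone array and four peripheral ultrasonic
    microphones, and assigns each vocalization to the emitting mouse.
    Implements frequency-domain delay-and-sum beamforming (coarse-to-fine
    grid scan with weighted-centroid refinement), a four-microphone
    TDOA/origin-curve localizer, and probabilistic emitter assignment via a
    Mouse Probability Index with per-method uncertainty calibration. Includes
    a ground-truthed synthetic acoustic-scene generator (chirp synthesis,
    fractional-delay propagation, sensor-noise models, mouse pose tracks)
    and downstream spatial-vocalization statistics (relative polar occurrence
    histograms with bootstrap significance, sex fractions, dominance
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
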