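Package: biosonarsim
Title: Time-Domain Simulation of Dolphin Biosonar Target Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale two-dimensional acoustic simulation of a dolphin
    echolocation click interacting with cylindrical targets that differ only
    in material composition (air-filled PVC, water-filled PVC, foam-ball
    arrays, closed-cell-foam-wrapped PVC). Provides a staggered-grid
    finite-difference time-domain solver for heterogeneous sound-speed and
    density fields with a graded-damping absorbing boundary, a calibrated
    finite-aperture surrogate for the directional emitted click, echo
    characterization (energy flux density, -10 dB duration, centroid
    frequency, RMS bandwidth, highlight structure, beam patterns and 3-dB
    beamwidths, directivity index, sliding energy-detector window), and
    exact binomial analysis of matching-to-sample behavioral trials with
    synthetic trial generation and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
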