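Package: sgrtrack
Title: Marker-Based Optical Surface Tracking for Upright Radiotherapy Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter- and intra-fractional setup accuracy of
    upright radiotherapy positioning from multi-camera optical surface
    tracking of labeled skin and thermoplastic-mask markers. Implements
    pinhole projection and extrinsic calibration by reprojection-error
    minimisation, pairwise triangulation, sub-pixel dark-marker centroid
    detection, rigid point-cloud registration (Kabsch and iterative closest
    point) with respiratory-marker temporal smoothing, six-degree-of-freedom
    displacement series, systematic/random setup-error statistics, beam
    delivery time under motion tolerances, and the Welch / Brown-Forsythe /
    Holm-Bonferroni comparison layer. A synthetic scene and motion simulator
    generates every pipeline input with known ground truth so the whole
    analysis is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
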