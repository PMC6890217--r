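Package: tripoint
Title: Tri-Point Landmark Registration and Accuracy Indicators for Guided Implant Placement
Version: 1.0.0
Authors@R: person("VDING", "Analysis Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assesses the accuracy of guided dental-implant placement from
    paired anatomical landmarks digitized in the preoperative (planned) and
    postoperative (real) CBCT image spaces. Constructs relative orthonormal
    coordinate frames from three landmark pairs, ranks landmark pairs by a
    triangle-congruence error metric with iterative worst-point elimination,
    reports a per-case registration system error from a held-out pair, and
    computes ten planned-versus-placed implant deviation indicators (HS, AD,
    CGD, CVD, CLD, CRD, AGD, AVD, ALD, ARD). Includes a synthetic-case
    generator with known ground truth, factor-sweep simulations for landmark
    count and spread, CSV input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
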