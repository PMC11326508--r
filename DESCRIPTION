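Package: spinemark
Title: Vertebra Landmark Detection and Cobb Angle Estimation for Scoliosis Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for keypoint-based vertebra landmark detection on
    anterior-posterior spinal radiographs: dual-coordinate (Cartesian centre +
    polar corner) ground-truth encoding and decoding with sub-pixel offsets,
    inter-vertebral interval supervision targets, sparse-to-dense vertebral
    line interpolation by arc-length-equidistant spline sampling, the composite
    multi-task training loss, a compact trainable encoder-decoder reference
    network, Cobb angle estimation from 68 landmarks, and an evaluation suite
    (mean detection error, self-adaptive mean detection error with Hungarian
    matching, and symmetric mean absolute percentage error). A parametric
    scoliotic-spine simulator with analytic ground-truth Cobb angles renders
    pseudo-radiographs so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
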