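Package: screwstrip
Title: Model-Based Prediction of Bone-Screw Thread-Stripping Torque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the thread-stripping torque of cancellous bone screws
    from intra-insertion torque, rotation and linear-position recordings.
    Identifies the host material's ultimate compressive strength by fitting a
    physical insertion-torque model with single-parameter linear least
    squares, converts the strength into a stripping-torque prediction (with
    optional stress-concentration correction), and evaluates predictions
    against measured stripping torques with correlation, Fisher-z,
    linear-calibration and Bland-Altman summaries. Includes a synthetic
    test-rig simulator (30 RPM insertion, 1 kHz sampling, encoder and
    draw-wire quantization, torque-sensor noise) so the full pipeline is
    testable without experimental data, plus CSV/YAML/JSON interfaces and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
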