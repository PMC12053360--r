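Package: flagrot
Title: Rotational Kinematics of Uniflagellate Cells from Pose-Tracking
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for marker-less pose-estimation output
    (DeepLabCut single-animal CSV) of rotating uniflagellate cells such as
    the Chlamydomonas reinhardtii uni1 mutant. Computes body-axis and
    flagellar angle time series from three tracked landmarks (flagellar tip,
    flagellar base, cell posterior), applies likelihood-based masking,
    unwraps the body angle to a cumulative rotation curve, estimates signed
    rotational velocity by least squares, classifies rotation direction
    (counterclockwise vs clockwise) with optional visual-inspection
    overrides, estimates flagellar beat and body rotational frequencies by
    FFT power-spectrum peak detection, and assembles per-condition cohort
    summaries (direction counts, top-k box statistics, percent reductions).
    Includes a ground-truthed synthetic trajectory generator emulating a
    cell rotating at a constant rate while its flagellar angle oscillates
    sinusoidally, with localization noise and likelihood dropout, for
    validation and worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
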