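Package: breathvoc
Title: Exhaled-Breath VOC Biomarker Discovery from PTR-TOF-MS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for volatile organic compound (VOC) biomarker
    discovery in exhaled breath measured by proton-transfer-reaction
    time-of-flight mass spectrometry (PTR-TOF-MS). Covers per-recording
    mass-axis recalibration against permeation-source calibrant ions,
    capnostat and cycle-count quality control, exhalation-phase spectrum
    selection from the water-adduct and biogenic tracer ions,
    Savitzky-Golay smoothing and peak picking, cross-sample peak
    alignment, reference-ion normalization, tentative [M+H]+ annotation,
    group-comparison statistics, and a resampled gradient-boosting
    feature-selection procedure with cross-maneuver overlap and
    leave-one-out cross-validated evaluation. Includes a synthetic-cohort
    generator that emulates a case-control breathomics study with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
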