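Package: gazerr
Title: Visual Recognition Error Analysis for Eye-Tracked Lesion Detection Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screen-based eye-tracking studies of lesion
    detection in medical images, built around colonoscopy polyp perception
    experiments. Detects gaze fixations from raw binocular sample streams with
    a dispersion/duration rule, classifies every participant-polyp encounter
    as a correct detection, a gaze error (lesion never fixated) or a cognitive
    error (fixated but not marked), and summarizes cohorts with per-polyp
    sensitivity, error composition and exact Clopper-Pearson confidence
    intervals plus Fisher or chi-square group comparisons. Includes a
    synthetic scanpath generator with known ground-truth labels so the whole
    pipeline is testable without access-restricted study data, cumulative
    fixation heat maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
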