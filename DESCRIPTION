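Package: nodeval
Title: Nodule-Level Validation of Lesion-Detection CAD Against
    Multi-Reader Reference Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating computer-aided detection (CAD) of
    pulmonary nodules on chest CT against a majority-vote multi-reader
    reference standard. Builds consensus references with exclusion lists
    from per-reader annotation tables, matches scored detections with a
    center-within-radius hit criterion, computes FROC curves, sensitivity
    at predefined false-positive rates and the Competition Performance
    Metric (CPM) with scan-level bootstrap confidence intervals, calibrates
    operating points to a target false-positive rate, and compares CAD
    against individual readers using leave-one-out references and paired
    permutation tests. A synthetic cohort generator simulates ground truth,
    heterogeneous reader panels and scored CAD output so the full pipeline
    can be exercised without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
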