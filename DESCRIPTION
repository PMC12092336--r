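Package: mapse3d
Title: Automatic 3D Mitral Annular Plane Systolic Excursion from Landmark
    Detection Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for automatic measurement of mitral
    annular plane systolic excursion (MAPSE) from time-resolved 3D mitral
    annulus landmark detections, as produced by deep-learning detectors on
    single-beat full-volume 3D transesophageal echocardiography.  Implements
    standardized view slicing at 60 degree rotations, arc-based wall
    aggregation, rotation correction onto the left-ventricular long axis,
    per-volume and per-cycle artifact filtering, and recording-level
    aggregation.  Companion statistics cover test-retest precision as the
    least significant change, method agreement through a linked-replicates
    Bland-Altman variance-component model, time-weighted averages for
    hemodynamic monitoring series, Spearman rank correlation, and derived
    hemodynamic indices (arterial elastance, single-beat end-systolic
    elastance, cardiac power output).  A synthetic annulus-motion generator
    emulates detection streams, replicate tables and monitoring series with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
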