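Package: dentition
Title: Prior-Knowledge Tooth Numbering for Dental Panoramic Radiograph Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns noisy tooth- and prosthesis-candidate bounding boxes from any
    object detector into a consistent universal-tooth-numbering (UTN) chart of a
    dental panoramic radiograph. Provides positional false-positive filtering,
    quadratic occlusal-curve fitting with a dentition-center fallback,
    assignment of approximate tooth numbers to prosthesis detections (inlay,
    crown, implant, bridge with 33:30:33 bridge segmentation), a piecewise
    prior-knowledge positional objective combined with detector confidence, and
    a deterministic coordinate-ascent search that selects one candidate or
    "missing" per tooth. Also includes object-detection evaluation metrics
    (IOU, greedy matching, all-point interpolated AP, mAP, F1) and a seeded
    synthetic dentition simulator so the whole pipeline is testable without
    radiographs or trained detector weights.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'dentition-package.R'
    'AllClasses.R'
    'candidate-io.R'
    'tooth-filter.R'
    'occlusal-geometry.R'
    'prosthesis-numbering.R'
    'prior-knowledge.R'
    'optimizer.R'
    'detection-metrics.R'
    'synthetic-dentition.R'
    'pipeline.R'
    'small-instances.R'
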