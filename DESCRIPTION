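Package: volecount
Title: Detection Evaluation and Tiled Counting for Aerial Burrow Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning object-detector output from unmanned-aircraft
    imagery into burrow counts. Implements axis-aligned box algebra (IoU and
    intersection-over-smaller), greedy detection/ground-truth matching with
    precision, recall, F1 and average precision, count-regression metrics
    (false positives per image, miss rate, log-average miss rate, mean absolute
    percentage error), IoU- and confidence-threshold calibration, overlapping
    tile-grid planning with IoS-based non-maximum suppression for scene-level
    counting, regional count validation, a flight-height/ground-sample-distance
    calculator, and a seeded synthetic-survey generator so every stage can be
    exercised without field imagery or a trained detector. Readers are provided
    for LabelMe rectangle annotations, COCO-style detection-results JSON and
    CSV detection tables, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
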