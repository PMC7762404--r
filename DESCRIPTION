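Package: medscore
Title: Mediterranean Diet Adherence Scoring from Weekly Food Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Mediterranean Diet Serving Score (MDSS) rule
    engine over weekly food diaries: a 31-category food/beverage taxonomy
    mapped onto 14 scoring groups with per-meal, daily and weekly rules, the
    weekly adherence total on a 0-24 scale, and traffic-light adherence
    bands. Ships a diary data model with JSON and CSV input/output, a seeded
    synthetic-diary generator with calibrated adherence profiles, evaluation
    metrics for multi-label food recognition (interpolated mean average
    precision and serving-size mean absolute percentage error),
    multi-annotator ground-truth aggregation, a label co-occurrence graph
    builder, and a bridge that assembles per-image recognizer output into
    scoreable diaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
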