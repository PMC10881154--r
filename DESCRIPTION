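Package: epispindle
Title: Spindle Orientation Quantification and Randomization Testing in Adult Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for oriented cell division in adult
    epidermis. Computes mitotic spindle angles from spindle-pole and
    basement-membrane annotations, classifies divisions as planar, oblique or
    perpendicular, and scores angle distributions against a uniform null with
    a Monte-Carlo two-sample Kolmogorov-Smirnov randomization score. Includes
    a Gaussian-simulation outlier test for rare-event frequencies, tissue
    morphometry (cell density, folding ratio, marker fractions), live-imaging
    division-track classification (telophase resolution and basal
    reintegration), tumor-cohort summaries, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
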