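Package: cohmap
Title: Quantitative Cytochrome Oxidase Histochemistry Brain Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative cytochrome oxidase (CO)
    histochemistry brain mapping in a 2x2 (surgery x drug) rodent cohort:
    densitometric calibration of 8-bit section images against a step tablet
    and thickness-graded tissue standards, polygon-ROI optical density
    measurement and conversion to CO activity, per-ROI factorial statistics
    with Cohen's d effect sizes, interregional CO-correlation (metabolic
    covariance) network construction and Fisher-z group comparison,
    white-matter-referenced lesion segmentation and serial-section
    volumetry, and brain-behavior correlation. A synthetic-data generator
    emulates the full study cohort (calibration materials, section images,
    ROI activity tables, behavior scores) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    car,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
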