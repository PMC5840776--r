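Package: rhoscreen
Title: RNAi Screen Scoring and Two-State Random-Walk Analysis of Cell
    Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for image-based RNAi screens of cell
    migration: wound (exclusion-zone) assay image scoring with plate
    Z-score hit classification, a two-state persistent random-walk model
    of single-cell migration with hidden-Markov EM fitting and state
    decoding, cell-shape descriptors from binary masks, and profiling of
    biosensor activity against distance from the cell edge and local
    protrusion/retraction velocity. Includes a synthetic-data generator
    that emulates every input with known ground truth, so all stages are
    testable without raw microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
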