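Package: neuroassay
Title: Functional Phenotyping of Cultured Neurons from MEA, Calcium
    Imaging and Scratch Assays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for three functional assays
    commonly used to phenotype patient-derived (iPSC) neuronal cultures:
    multi-electrode array (MEA) extracellular recordings (first-order
    Butterworth band-pass filtering, adaptive rolling-standard-deviation
    spike thresholding, per-well firing-rate summaries), somatic calcium
    imaging (candidate transient delimitation by monotonically decreasing
    flanks, triangle-area relevance scoring, active-cell filtering, event
    frequencies), and scratch wound-healing assays (reinvasion counts in a
    standardized region of interest, recovery-rate estimation). A seeded
    synthetic-data generator produces ground-truth-labelled cohorts so
    every stage is testable without instrument data, and a statistics
    layer provides one-way ANOVA with Tukey HSD and mixed repeated-
    measures ANOVA for case/control comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
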