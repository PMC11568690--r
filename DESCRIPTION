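Package: coduco
Title: Decoding of Combinatorial Dual-Color In Situ Signals in Single Cells
Version: 0.1.0
Authors@R:
    person("CoDuCo", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An image-analysis pipeline for combinatorial dual-color (two
    fluorophores per marker) in situ hybridization of rolling-circle
    products. Decodes dual-color-encoded spots in multichannel fluorescence
    images, registers and subtracts post-strip background scans, segments
    nuclei and expands them to cell borders, assigns decoded transcripts to
    cells, classifies cells (tumor cell, blood cell, artefact, false
    positive, negative) with a random forest trained on per-cell marker
    counts, and summarizes per-cell expression. Ships a synthetic-image and
    synthetic-count generator with full ground truth so every stage is
    testable without proprietary microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
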