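Package: deldose
Title: Dose-Response Activity-Based DNA-Encoded Library Screening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for dose-response
    activity-based screening of solid-phase DNA-encoded libraries (DELs)
    in microfluidic droplets. Enumerates two-cycle combinatorial libraries
    with DNA encoding tags and molecular property profiles, plants
    ground-truth inhibitor series structured by shared building blocks,
    simulates UV-dose-dependent compound release and enzyme
    fractional-activity fluorescence in droplets, applies dynamic
    mean-minus-N-sigma sorting thresholds with hit-rate and
    library-equivalent accounting, deconvolutes hit-bead tag reads into
    per-member replicate counts (k classes) and per-building-block
    cumulative enrichment, tiers building blocks by dose-conforming
    behavior across high and low UV screens, and validates hits with
    four-parameter logistic IC50 fits and planted-truth recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
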