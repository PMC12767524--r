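Package: promnex
Title: Base-Resolution ChIP-Nexus Footprint Analysis at Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for base-resolution, strand-specific
    ChIP-nexus/ChIP-exo footprints at promoters. Builds stop-base coverage
    from aligned reads with barcode deduplication, annotates transcription
    start sites from CAGE tag counts (power-law normalization, distance
    clustering, interquantile boundaries, consensus aggregation), detects
    footprint contact midpoints from paired strand peaks, classifies
    promoters by core promoter elements (TATA, Inr, DPE, MTE, PB, DRE,
    Ohler 1/6/7, TCT), clusters TBP binding-profile shapes with element
    enrichment, computes transcription-normalized occupancy statistics,
    and fits paused Pol II half-lives from time-course coverage. Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    minpack.lm,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
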