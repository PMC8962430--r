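Package: swathloc
Title: Apical/Basolateral Membrane Protein Localization from Two-Fraction
    SWATH Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines whether membrane proteins localize to the apical
    membrane, the basolateral membrane, or both, from paired two-fraction
    data-independent-acquisition (SWATH) proteomics. Rolls transition-level
    extracted peak areas up to protein-level quantities with tryptic
    peptide selection and transition-efficiency normalization, computes
    per-animal basolateral/apical (B/A) ratios, calibrates the two class
    decision borders as density intersections of normal fits to a
    literature-validated reference panel, and applies a UniProt-style
    subcellular-location keyword filter to produce the final localization
    call table. Ships a synthetic-data generator that emulates the full
    experiment so every stage is testable without raw mass-spectrometry
    data, plus a curated mouse-liver call table and reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
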