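Package: faangr
Title: Tiered Metadata Rulesets, Ontology-Aware Validation and Archive
    Conversion for Farmed-Animal Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An offline engine for the FAANG-style metadata standards used in
    farmed and companion animal genomics.  Provides a versioned JSON ruleset
    format with mandatory/recommended/optional requirement tiers, an in-memory
    ontology graph with descendant queries and free-text term matching,
    validation of animal/specimen/experiment records including the controlled
    missing-value vocabulary and crossbreed ("breed sire x breed dam")
    nomenclature, classification of records against full and legacy standards
    with version labelling, spreadsheet and JSON record intake, annotated
    validation reports, and conversion of validated records into
    BioSamples-style JSON and ENA-style experiment XML submission documents.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
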