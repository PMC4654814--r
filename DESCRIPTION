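Package: rctcnv
Title: Targeted Copy-Number Screening of Reverse Cholesterol Transport Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted copy-number variation (CNV)
    screening of reverse cholesterol transport (RCT) pathway genes from
    multiplex ligation-dependent probe amplification (MLPA) peak tables and
    orthogonal molecular-count assays. Provides reference-probe
    normalization, cohort-based reference-sample selection, copy-number
    ratio computation with probe and sample quality control, threshold and
    anchored-cluster copy calling, cross-platform confirmation with
    ligation-site SNP artifact diagnosis, NCEP ATP III lipid phenotype
    classification, and CNV-expression dosage association. Includes a
    synthetic-data generator emulating the dosage-assay signal model so
    every stage is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
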