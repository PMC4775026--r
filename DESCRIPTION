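Package: alportdx
Title: Differential Diagnosis Toolkit for Alport-Related Type IV Collagenopathies
Version: 0.3.0
Authors@R:
    person("Kovacs", "Lab Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variant interpretation and family-level diagnosis for the type IV
    collagen nephropathies (Alport syndrome and familial benign hematuria).
    Parses HGVS cDNA and protein descriptions for COL4A3, COL4A4 and COL4A5,
    assigns molecular consequences including splice-site annotation and the
    collagenous-domain glycine rule, applies a four-criterion pathogenicity
    rule engine with pedigree segregation testing, calls the inheritance mode
    of a family (X-linked Alport, autosomal semi-dominant Alport, FBH), and
    quantifies genotype severity with a functional triple-helix dosage model.
    Includes amplicon-panel coverage QC, a synthetic pedigree and cohort
    simulator for end-to-end validation, packaged variant fixture tables, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
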