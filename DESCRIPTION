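Package: qsarpipe
Title: QSAR Model Building, Validation and Ligand-Design Screening for
    Cytotoxicity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete quantitative structure-activity relationship (QSAR)
    modelling pipeline for small cytotoxicity datasets: descriptor
    pretreatment (constant and inter-correlation filters), deterministic
    Kennard-Stone train/test division, genetic-function-algorithm descriptor
    selection under the Friedman lack-of-fit score, ordinary least-squares
    multilinear regression with a full ANOVA and diagnostic suite (VIF, mean
    effects, leave-one-out Q2, external R2), Y-randomization robustness
    testing with the cRp2 coefficient, a leverage-based applicability domain
    (Williams plot data), and model-based screening of designed ligands. A
    published five-descriptor model of imidazol-5-one cytotoxicity against
    the HCT116 colorectal cancer cell line is bundled as a fixture, together
    with a synthetic-data generator that emulates the statistical structure
    of such datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
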