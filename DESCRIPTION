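Package: lggproteo
Title: Proteogenomic Subtyping of Low-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream proteogenomic analysis of diffuse low-grade glioma (LGG)
    molecular subtypes. Implements complete-case filtering of tandem-mass-tag
    protein abundance matrices, Welch-based differential expression/abundance
    testing with fold-change and Benjamini-Hochberg gates, chromosome-arm
    localization of expression changes with Fisher enrichment tests, a combined
    1p/19q dosage z-score against a normal-brain reference, RNA-protein
    correlation by arm, directional-concordance selection of subtype marker
    panels, a ridge-penalized multinomial subtype classifier with stratified
    cross-validation and ROC/AUC, MAD-based feature selection with hierarchical
    clustering, and a synthetic proteogenomic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
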