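Package: gastropanel
Title: Targeted-Panel Molecular Subtyping of Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for classifying gastric adenocarcinoma samples measured
    on a 107-gene targeted expression panel. Reads nCounter-style RCC count
    files, applies sample-level quality control, removes cartridge batch
    effects with RUV-III anchored on technical replicates and data-driven
    negative-control genes, maps per-gene distributions onto a reference
    cohort with feature-specific quantile normalization, and assigns
    probabilistic TCGA (CIN/EBV/GS/MSI) and tumour-microenvironment
    (High/Low) subtype scores. Includes the study's downstream analytics:
    pentaplex microsatellite-instability calling, tumour-organoid
    concordance statistics, four-parameter logistic dose-response fitting
    with drug sensitivity scores, hypergeometric over-representation
    analysis with enrichment networks, and subtype-drug association with
    target-pathway pooling. A synthetic-data generator emulates panel runs,
    reference cohorts, dose-response plates and MSI marker profiles so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
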