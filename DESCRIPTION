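Package: aqmarker
Title: Aqueous Humor Proteomic Biomarker Workflow for Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for discovering and validating aqueous humor
    protein biomarkers across diabetic retinopathy stages (nonproliferative
    retinopathy, proliferative retinopathy, neovascular glaucoma).
    Covers differential-expression calling on label-free and isobaric-tag
    quantification platforms, empirical-Bayes batch integration across
    platforms, rule-based design of multiple-reaction-monitoring (MRM)
    transitions from a FASTA database, the targeted-MS quality-control
    cascade (spike-in normalization, detection, sample and CV filters),
    rank-based biomarker statistics (Wilcoxon, fold change, ROC/AUC, tiering),
    clinical covariate statistics (exact and chi-square tests, odds ratios,
    adjusted regression, stratified re-testing), stage-wise single-sample
    gene-set enrichment, and a synthetic cohort generator that reproduces the
    statistical structure the analysis assumes for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
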