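Package: ihdrisk
Title: Opportunistic Ischemic Heart Disease Risk Assessment from CT Body
    Composition and Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for opportunistic ischemic heart disease (IHD) risk
    assessment from single abdominopelvic CT slices at the L3 vertebral
    level combined with electronic medical record (EMR) data.  Provides
    deterministic CT preprocessing (Hounsfield-unit clipping,
    window/level normalization, body-mask extraction), body-composition
    metrics (tissue areas, radiodensity, VAT/SAT ratio, Dice overlap,
    RMS coefficient of variation), a tissue-saliency statistic that
    aggregates pixel-gradient attributions of a differentiable risk
    scorer by tissue class and contrasts observed with expected saliency
    fractions, EMR feature engineering (time-weighted vitals and labs,
    ontology code roll-ups, Charlson comorbidity index, correlation
    pruning), cohort construction with outcome labeling and stratified
    splits, penalized-logistic and gradient-boosted risk models with
    stacking fusion, coefficient-table evaluators for published risk
    scores, and evaluation statistics (AUROC, AUCPR, stratified
    bootstrap confidence intervals, DeLong comparison, Youden operating
    points).  Synthetic L3 phantom and EMR cohort generators with known
    planted signal make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
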