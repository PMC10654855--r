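Package: notepredict
Title: Text-Based Featurization and Prediction Benchmarking for GP EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building patient-level prognostic prediction models from
    general-practitioner electronic health records that contain both structured
    events and free-text notes. Implements a reproducible clinical-text
    featurization pipeline (preprocessing, tokenization, document-frequency
    vocabulary pruning, binary bag-of-words and TF-IDF representations, and
    dictionary-based clinical concept extraction with ConText-style
    negation/hypothetical/historical/experiencer detection for Dutch notes),
    simplified OMOP-CDM-style cohort construction with observation-time and
    follow-up exclusions, demographic and clinical-event covariates, and a full
    benchmark harness that trains L1 logistic regression, gradient boosting and
    random forest models over seven structured/text feature-set combinations
    with subject-level internal and external validation. Includes a seeded
    synthetic EHR generator with planted outcome signals and distribution shift
    between two emulated EHR systems, plus evaluation utilities (AUROC, AUPRC,
    Brier score, F1-maximizing threshold metrics, median-centering,
    Bonferroni-adjusted Wilcoxon comparisons, predictive-multiplicity
    correlations and feature importance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    glmnet,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'text.R'
    'concepts.R'
    'evaluation.R'
    'structured.R'
    'experiment.R'
    'io.R'
    'synthetic.R'
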