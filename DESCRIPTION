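Package: disoPPI
Title: Sequence-Based Prediction of Protein-Protein Interactions Involving
    Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Disorder-aware feature encoding and leakage-aware evaluation for
    predicting protein-protein interactions (PPIs) that involve intrinsically
    disordered proteins (IDPs). Protein pairs are encoded as 940-dimensional
    vectors combining pseudo amino acid composition (PAAC, five propensity
    scales, lambda = 50) with dipeptide composition; interaction datasets are
    built with length and annotation filters, 40 percent identity redundancy
    reduction, degree-balanced negative sampling and component-disjoint (C2)
    train/test splits; random forest, gradient boosting, regularized linear
    and support vector classifiers are trained and scored with an
    imbalance-aware metric suite (AUC, AUPRC, accuracy, F, MCC, precision,
    recall, fall-out). A synthetic sequence and network generator with a
    plantable charge-complementarity interaction rule makes the whole
    pipeline testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ranger,
    xgboost,
    glmnet,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
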