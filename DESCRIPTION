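Package: stageSig
Title: Expression Signature Selection for Tumour Stage with a GA-Wrapped SVM
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects small microRNA expression signatures that discriminate
    early-stage from advanced-stage tumours. A soft-margin RBF support vector
    machine is wrapped in an inheritable bi-objective combinatorial genetic
    algorithm (IBCGA) that evolves fixed-cardinality feature subsets together
    with the SVM cost and kernel-width parameters, using orthogonal-array
    crossover and elite-protected mutation, and inherits solutions across
    signature sizes. Includes stratified cross-validation machinery with
    accuracy, sensitivity, specificity, Matthews correlation coefficient and
    ROC/AUC; main-effect-difference (MED) ranking of selected features via
    orthogonal experimental design; single-feature knockout analysis;
    information-gain and standard-classifier baselines; a synthetic two-class
    cohort generator with planted differential features; and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    randomForest,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
biocViews: Classification, FeatureExtraction, Transcriptomics,
    GeneExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
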