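Package: rdscreen
Title: Questionnaire Answer-Pattern Screening for Rare Disease Diagnostic Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern-recognition pipeline for detecting rare-disease answer
    patterns in 53-item patient questionnaires. Encodes each completed
    questionnaire into a 55-element feature vector (53 ordinal answers on a
    1-4 scale, gender, age), trains four base binary classifiers (degree-3
    polynomial-kernel support vector machine, random forest, logistic
    regression, linear discriminant analysis) on each of three pairwise
    disease-group subsets, fuses their coded diagnoses and probabilities with
    a stacked meta-classifier trained on out-of-fold predictions, and
    evaluates by stratified 10-fold cross-validation with confusion matrices,
    sensitivity/specificity, ROC/AUC, and a cross-subset aggregate rare-disease
    sensitivity. Includes a synthetic cohort generator emulating per-group
    categorical answer distributions with controllable group separation, and a
    command-line interface for simulation, training, evaluation and per-patient
    probability-triple prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
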