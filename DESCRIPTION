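Package: sosampler
Title: Supervised Over-Sampling for Imbalanced Binding-Residue Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for class-imbalanced learning centred on supervised
    over-sampling (SOS), in which interpolated minority-class candidates are
    filtered by the confidence of a classifier trained on the original data.
    Includes the standard comparison samplers (random over-sampling, SMOTE,
    ADASYN), a per-residue feature pipeline for protein-nucleotide
    binding-residue prediction (logistic-normalised PSSM profiles and
    predicted secondary structure over a sliding window), threshold-dependent
    evaluation (sensitivity, specificity, accuracy, MCC, AUC) under
    MCC-maximising or balanced threshold selection, a group-aware
    cross-validation harness, synthetic data generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
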