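Package: ihdri
Title: Fair and Explainable Recurrent Risk Models for Ischemic Heart Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prognosis of ischemic heart disease from tabular
    clinical records in the UCI Heart Disease schema: synthetic cohort
    simulation with controllable demographic bias, fuzzy-membership multiple
    imputation, leakage-safe preprocessing (min-max scaling, one-hot
    encoding, stratified k-fold plans), a residual-attention bidirectional
    LSTM classifier with transfer-learning initialization and a
    fairness-aware inverse-frequency reweighted loss, exact and sampled
    Shapley-value attribution, and a cross-validation / ablation / fairness
    reporting harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
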