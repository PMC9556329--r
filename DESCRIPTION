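Package: immunoMPR
Title: Peripheral Blood Immunophenotype Prediction of Major Pathological
    Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploratory biomarker analysis of neoadjuvant
    checkpoint-inhibitor trials in resectable non-small cell lung cancer.
    Builds marker-combination feature spaces from multi-tube flow-cytometry
    abundance tables, ranks features by an information-divergence importance
    score under random subsampling of extreme responders and non-responders,
    fits a group-lasso penalized generalized additive logistic model of
    major pathological response (MPR), and computes the trial endpoint
    statistics: MPR and pCR rates with exact confidence intervals, Fisher
    and Freeman-Halton exact contingency tests, Welch tests, tumor
    mutational burden, Kaplan-Meier survival and exact binomial design
    power. A synthetic cohort generator with a latent cell-population
    mixture model provides fully reproducible inputs with planted effects
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
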