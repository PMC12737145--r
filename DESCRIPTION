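Package: breastdose
Title: Personalized Breast Absorbed-Dose Modelling and PSO-Tuned
    Tree-Ensemble Benchmarking for Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the patient-specific radiation dose
    absorbed by breast tissue during chest computed-tomography
    examinations. Implements a dose-length-product (DLP) based internal
    radiation model with min-max normalized anthropometric factors (BMI,
    mammographic breast thickness, age), a synthetic patient-cohort
    generator with truncated marginals and a Gaussian copula, a
    from-scratch particle swarm optimizer for mixed integer/continuous
    hyperparameter spaces, a five-family tree-ensemble regression
    benchmark (histogram gradient boosting, classical gradient boosting,
    extremely randomized trees, AdaBoost.R2, random forest), and a local
    surrogate (LIME-style) explainer for single predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xgboost,
    ranger,
    Rcpp,
    ggplot2,
    rlang
LinkingTo:
    Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
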