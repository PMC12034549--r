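Package: ppdens
Title: Ensemble Neural Networks for Postpartum Depression Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts postpartum depression (PPD) risk from integer-coded
    questionnaire responses with a weighted ensemble of two backpropagation
    multilayer perceptrons: a plain fully-connected network (FCNN) and the
    same architecture trained with inverted dropout (DNN). Ensemble weights
    are derived from the members' training-set accuracies and dropout rates.
    Includes the ten-attribute questionnaire schema and CSV tooling,
    stratified train/test splitting, a Gaussian-copula generator for
    synthetic questionnaire datasets with a controlled class balance and
    pairwise correlation structure, a nine-metric confusion-matrix
    evaluation suite, repeated-run benchmarking with Mann-Whitney U
    comparisons against baseline classifiers, and an ablation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
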