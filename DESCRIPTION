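Package: crowdtruth
Title: Quality Assessment and Truth Inference for Crowdsourced Health
    Surveillance Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of crowd-generated labels and
    inferring truth labels for public-health surveillance tasks labeled on
    microtask platforms such as Amazon Mechanical Turk. Provides a synthetic
    crowd-labeling simulator with known ground truth (confusion-matrix and
    ability/difficulty worker noise models, heavy-tailed worker activity,
    spammer and adversarial workers, class-informative task metadata),
    HIT validation and label-matrix construction, entropy-based label
    consistency scoring, four unsupervised truth-inference models (majority
    vote, Dawid-Skene, GLAD, Raykar), a supervised meta-feature inference
    layer with nested cross-validation, pool-based active learning with
    uncertainty sampling, and exact Shapley-value feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    generics,
    ggplot2,
    withr,
    stats,
    utils,
    nnet,
    e1071,
    ranger,
    xgboost,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
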