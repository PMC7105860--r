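Package: scaleforge
Title: Predictive-Oriented Construction of Binary Psychometric Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building diagnostic questionnaires that balance
    explanatory structure with out-of-sample predictive power. Implements a
    single-hidden-layer logistic network trained with resilient
    backpropagation (RPROP), class-balanced Monte-Carlo cross-validation with
    an architecture search over hidden-layer sizes, ROC analysis with the
    (0,1)-criterion cutoff, a knowledge-based randomized item-selection
    algorithm that grows a fixed set of theory-anchored items, and an
    explanatory evaluation layer (principal components with Varimax rotation,
    Cronbach's alpha, Kaiser-Meyer-Olkin adequacy) for binary items. Includes
    a latent-factor generator of synthetic questionnaire datasets, predictive
    mean matching imputation for sparse missingness, and demographic
    comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
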