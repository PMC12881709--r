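Package: pestisdm
Title: Integrated Species Distribution Modelling of Tree Pest and Disease
    Burdens with Causal Covariate Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping spatial burdens of tree pests and diseases by
    fusing repeat-visit presence-absence surveys with opportunistic
    presence-background reports in a single log-Gaussian Cox process.  The
    shared process model is log-linear in engineered landscape covariates plus
    a Matern Gaussian random field represented through a sparse
    stochastic-partial-differential-equation (SPDE) precision matrix; the
    presence-background stream carries a second field absorbing reporting
    bias.  Inference is empirical-Bayes Laplace approximation with penalised
    complexity priors on the field hyperparameters.  The package also provides
    covariate engineering (Gaussian-kernel connectivity, distance-to-feature,
    per-cell area and edge length, standardisation), directed-acyclic-graph
    causal analysis (d-separation, minimal back-door adjustment sets,
    DAG-sequence sensitivity), WAIC-based covariate search, Huber robust
    regression of intensity against host cover, and a synthetic-landscape
    generator with known causal structure so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
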