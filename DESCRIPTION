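Package: painvlab
Title: Virtual-Patient Simulation of Pregabalin Pain Response in Painful
    Diabetic Peripheral Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cluster-then-simulate pipeline for predicting weekly pain
    trajectories of pregabalin-treated patients with painful diabetic
    peripheral neuropathy (pDPN). Observational-study patients are grouped by
    hierarchical clustering on a Gower distance over mixed-type baseline
    covariates; randomized-trial patients are matched to clusters by coarsened
    exact matching with multivariate L1 imbalance diagnostics; per-cluster
    lagged regressions of weekly pain on antecedent pain, sleep interference,
    dose and baseline characteristics are selected stepwise and re-estimated
    with penalized (LASSO-family) methods; novel patients are assigned to a
    cluster by an instance-based ensemble and simulated as a Monte-Carlo cloud
    of virtual instances whose time-varying covariates are drawn from
    k-nearest-neighbour empirical distributions; responder status beyond the
    6-week horizon is extrapolated from trajectory monotonicity against
    long-duration trial patients. A synthetic-cohort generator reproduces the
    statistical structure the pipeline assumes so every stage is testable
    without proprietary study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    cluster,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
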