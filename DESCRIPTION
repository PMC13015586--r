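Package: effortrl
Title: Computational Modelling of Effort-Based Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of choice behavior on
    the Effort Expenditure for Rewards Task (EEfRT). Implements two subjective-value
    models and a temporal-difference reinforcement-learning (Q-learning) model of
    trial-by-trial effort-based choice with a softmax policy, fits them jointly
    across cohorts by Hamiltonian Monte Carlo with non-centered hierarchical priors,
    compares models by bridge-sampling marginal likelihood and Pareto-smoothed
    importance-sampling leave-one-out predictive density, and classifies cohorts
    from per-subject maximum a posteriori parameter vectors via PCA, MANOVA and
    leave-one-out cross-validated linear discriminant analysis with DeLong ROC
    confidence intervals. Includes a synthetic-data generator emulating the task
    so every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
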