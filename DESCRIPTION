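Package: banditfit
Title: Reinforcement-Learning Analysis of Non-Stationary Three-Armed Bandit Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood analysis of choice behavior in
    non-stationary multi-armed bandit tasks of the kind used to study the
    exploration-exploitation trade-off in rodents. Provides a task generator
    with counterbalanced block schedules and probabilistic rewards; a family of
    trial-by-trial learning models (Q-learning with and without forgetting,
    epsilon-greedy action selection, uncertainty-bonus directed exploration,
    and a meta-learning model in which the softmax inverse temperature tracks
    accumulated reward prediction errors); per-subject maximum-likelihood
    fitting from a grid of starting points with AIC/BIC and likelihood-ratio
    model comparison; behavioral exploration indices (performance, win-shift,
    lose-shift) and their within-block dynamics; parameter-recovery
    experiments; and an executable check of the exact equivalence between
    rescaling rewards and rescaling the inverse temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
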