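Package: rlddm
Title: Reinforcement-Learning Drift-Diffusion Modelling of Explore/Exploit
    Choice in Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing explore/exploit choice behaviour in
    two-armed probabilistic reversal-learning tasks with a
    reinforcement-learning drift-diffusion model (RLDDM). Provides the
    Wiener first-passage-time likelihood, delta-rule value learning with
    separate learning rates for positive and negative prediction errors,
    hierarchical Bayesian estimation with condition contrasts and DIC
    model comparison, posterior-predictive checks and parameter recovery,
    exploratory-choice statistics (P(Explore), P(Reward)), generative
    simulation of task cohorts, and a voxelwise R-map connectivity
    procedure with permutation testing and stimulation-volume heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
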