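Package: acqrl
Title: Actor/Critic and Q-Learning Hybrid Models for a Two-Stage Markov
    Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a two-stage Markov decision task with interleaved
    passive and active trials and probabilistic reversals, and implements the
    full nested family of reinforcement-learning models for it: actor/critic,
    Q-learning, critic/Q-learner and actor/critic/Q-learner hybrids with
    TD(lambda) eligibility traces, an optional model-based planner, and an
    augmented softmax policy with perseveration and side biases. Provides
    maximum-likelihood fitting with AICc factorial model comparison, parameter
    and model recovery harnesses, behavioral statistics (accuracy with
    exclusions, chance tests, model-derived logistic and reaction-time
    regressions, choice curves), and construction of model-derived fMRI
    parametric regressors convolved with a canonical double-gamma
    hemodynamic-response function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
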