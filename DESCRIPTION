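Package: predpreyRL
Title: Predator-Prey Lattice Dynamics with Deep Q-Learning Co-Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based predator-prey ecosystem on a periodic square
    lattice with asynchronous Monte Carlo updating, plus a deep
    reinforcement-learning layer in which each species shares a small
    convolutional Q-network trained from a population replay memory.
    Provides the stochastic interaction rules (movement, predation,
    reproduction, metabolism, ageing), Chebyshev-shell reward shaping,
    epsilon-greedy behaviour policies, DQN training with a pseudo-Huber
    loss and Adam, and an experiment layer reproducing learning /
    no-learning case studies, time-series summaries, LOWESS trends and
    spatial snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
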