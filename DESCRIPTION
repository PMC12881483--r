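Package: twostepddm
Title: Reinforcement-Learning Drift-Diffusion Modelling of Two-Step Task
    Decisions for Self and Others
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the deterministic-transition two-step task with
    drifting rewards, fits a hybrid model-based/model-free reinforcement-
    learning drift-diffusion model (RLDDM) jointly to choices and response
    times by maximum a posteriori estimation with a genetic algorithm,
    and provides the surrounding analysis pipeline: a synthetic cohort
    generator with planted self-other effects, exclusion rules with a
    random-agent likelihood null, hierarchical Bayesian logistic
    regressions of stay probabilities, parameter recovery, posterior
    predictive checks, selective parameter-muting simulations, social
    value orientation scoring, and bootstrap mediation analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    rjags,
    coda
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
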