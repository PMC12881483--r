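#' Synthetic cohort configuration
#'
#' Two modes.  `"recovery"` draws every parameter independently from the
#' uniform ranges used for parameter recovery: `U(-0.5, 1)` for the drift
#' weights, `U(-1, 0.5)` for the two Other-Self differences, `U(0, 1)` for
#' the learning rates, `U(-1.2, 1.2)` for the stickiness parameters,
#' `U(0.9, 2)` for the boundary and `U(0.02, 0.55)` s for the non-decision
#' time.  `"planted"` draws a 92-agent cohort with heterogeneous parameters
#' centred on realistic group values and plants three effects: a mean
#' Other-Self gap in the model-based weight, a mean Other-Self gap in
#' non-decision time (with the two gaps correlated so that the
#' non-decision-time gap partially mediates the weight gap), and a
#' correlation between SVO and the Self-Other model-based-weight gap via a
#' Gaussian copula, so every marginal stays inside its admissible range.
#'
#' @param mode `"planted"` or `"recovery"`.
#' @param n_agents Cohort size (92 in planted mode, 100 in recovery mode).
#' @param planted_diff_mb Mean Other-Self model-based-weight gap.
#' @param planted_diff_ndt Mean Other-Self non-decision-time gap (s).
#' @param planted_diff_alpha Mean Other-Self learning-rate gap.
#' @param svo_gap_cor Target correlation between SVO and the *Self-Other*
#'   model-based-weight gap (negative: prosocials show smaller gaps).
#' @param mediation_slope Slope of the model-based-weight gap on the
#'   non-decision-time gap (units: weight per second).
#' @param level_cor Person-level correlation between Self non-decision time
#'   and Self model-based weight.
#' @param keypress_p Second-stage keypress success probability.
#' @param miss_rate First-stage lapse/miss probability per trial.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(mode = c("planted", "recovery"),
                          n_agents = if (mode[1] == "recovery") 100L else 92L,
                          planted_diff_mb = -0.13, planted_diff_ndt = -0.04,
                          planted_diff_alpha = -0.08, svo_gap_cor = -0.5,
                          mediation_slope = 1.15, level_cor = 0.3,
                          keypress_p = if (mode[1] == "recovery") 1 else 0.98,
                          miss_rate = if (mode[1] == "recovery") 0 else 0.02,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (abs(svo_gap_cor) >= 1) stop("|svo_gap_cor| must be < 1")
  structure(list(mode = mode, n_agents = as.integer(n_agents),
                 planted_diff_mb = planted_diff_mb,
                 planted_diff_ndt = planted_diff_ndt,
                 planted_diff_alpha = planted_diff_alpha,
                 svo_gap_cor = svo_gap_cor,
                 mediation_slope = mediation_slope, level_cor = level_cor,
                 keypress_p = keypress_p, miss_rate = miss_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# inverse CDF of a truncated normal (used by the Gaussian copula)
qtruncnorm_ <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

#' Sample a cohort of agent specifications
#'
#' See [cohort_config()] for the two sampling modes.  Planted-mode draws
#' respect the search-space boxes by clipping; SVO angles are drawn from a
#' truncated Normal (mean 25 deg, SD 15 deg) over the instrument range
#' `[-16.26, 61.39]` and tied to the model-based-weight gap through a
#' Gaussian copula on the latent normals.
#'
#' @param config A [cohort_config()].
#' @return List of agent specs, each with `id`, `params` (named 14-vector),
#'   `svo`, `keypress_p`, `miss_rate`.  Empty list when `n_agents = 0`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_agents
  if (n == 0) return(list())
  if (config$mode == "recovery") {
    draw <- function(lo, hi) stats::runif(n, lo, hi)
    pm <- cbind(beta_mb_self = draw(-0.5, 1), beta_mf_self = draw(-0.5, 1),
                diff_mb = draw(-1, 0.5), diff_mf = draw(-1, 0.5),
                alpha_self = draw(0, 1), alpha_other = draw(0, 1),
                pi_self = draw(-1.2, 1.2), pi_other = draw(-1.2, 1.2),
                rho_self = draw(-1.2, 1.2), rho_other = draw(-1.2, 1.2),
                bound_self = draw(0.9, 2), bound_other = draw(0.9, 2),
                ndt_self = draw(0.02, 0.55), ndt_other = draw(0.02, 0.55))
    svo <- qtruncnorm_(stats::runif(n), 25, 15, -16.26, 61.39)
  } else {
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    # latent normals: z_svo drives SVO; the weight-gap residual is built
    # from z_svo plus independent noise so the target correlation holds
    z_svo <- stats::rnorm(n)
    svo <- qtruncnorm_(stats::pnorm(z_svo), 25, 15, -16.26, 61.39)
    ndt_self <- clip(stats::rnorm(n, 0.28, 0.07), 0.05, 0.8)
    gap_ndt <- stats::rnorm(n, config$planted_diff_ndt, 0.06)
    ndt_other <- clip(ndt_self + gap_ndt, 0.02, 0.9)
    # model-based weight: person level correlated with ndt level; gap
    # partially driven by the ndt gap (mediation) and tied to SVO
    z_lvl <- config$level_cor * scale(ndt_self)[, 1] +
      sqrt(1 - config$level_cor^2) * stats::rnorm(n)
    beta_mb_self <- 0.37 + 0.16 * z_lvl
    sd_total <- 0.18
    struct_sd <- config$mediation_slope * 0.06
    sd_resid <- sqrt(max(sd_total^2 - struct_sd^2, 0.04^2))
    # svo correlates with the Self-Other gap (= -diff_mb)
    c_resid <- clip(-config$svo_gap_cor * sd_total / sd_resid, -0.99, 0.99)
    resid <- sd_resid * (c_resid * z_svo +
                           sqrt(1 - c_resid^2) * stats::rnorm(n))
    diff_mb <- config$planted_diff_mb +
      config$mediation_slope * (gap_ndt - config$planted_diff_ndt) + resid
    diff_mb <- clip(diff_mb, -1, 1)
    alpha_self <- clip(stats::rnorm(n, 0.65, 0.22), 0.02, 0.98)
    alpha_other <- clip(alpha_self + stats::rnorm(n, config$planted_diff_alpha,
                                                  0.15), 0.02, 0.98)
    bound_self <- clip(stats::rnorm(n, 1.4, 0.25), 0.9, 2)
    bound_other <- clip(bound_self + stats::rnorm(n, 0, 0.12), 0.9, 2)
    pi_self <- stats::rnorm(n, 0.10, 0.30)
    rho_self <- stats::rnorm(n, 0.05, 0.30)
    pm <- cbind(beta_mb_self = beta_mb_self,
                beta_mf_self = stats::rnorm(n, 0.30, 0.15),
                diff_mb = diff_mb,
                diff_mf = stats::rnorm(n, 0, 0.10),
                alpha_self = alpha_self, alpha_other = alpha_other,
                pi_self = pi_self,
                pi_other = pi_self + stats::rnorm(n, 0, 0.15),
                rho_self = rho_self,
                rho_other = rho_self + stats::rnorm(n, 0, 0.15),
                bound_self = bound_self, bound_other = bound_other,
                ndt_self = ndt_self, ndt_other = ndt_other)
  }
  lapply(seq_len(n), function(i) {
    p <- pm[i, ]
    names(p) <- param_names()
    list(id = i, params = p, svo = svo[i],
         keypress_p = config$keypress_p, miss_rate = config$miss_rate)
  })
}

#' Forward-simulate one agent's session
#'
#' Runs the RLDDM forward on a scaffold: per trial the net drift is
#' computed from the agent's condition parameters and learner state, a
#' (choice, RT) pair is sampled by Euler-Maruyama diffusion, first-stage
#' lapses and second-stage keypress failures are applied, the reward is
#' read from the walk, and the learner is updated.
#'
#' @param agent Agent spec from [sample_cohort()], or any list with
#'   `params` and optionally `keypress_p`, `miss_rate`.
#' @param scaffold Scaffold data frame from
#'   [generate_trial_sequence_pair()].
#' @param dest Transition matrix.
#' @param seed Optional integer seed.
#' @param dt Diffusion step (s).
#' @param config A [task_config()].
#' @return Session data frame: one row per trial with columns `trial`,
#'   `block`, `condition`, `s1`, `a1`, `key`, `rt_ms`, `s2`, `keypress`,
#'   `reward`, `valid`, `vnet`.
#' @export
simulate_agent_session <- function(agent, scaffold,
                                   dest = make_transition_structure(),
                                   seed = NULL, dt = 1e-3,
                                   config = task_config()) {
  if (!is.null(seed)) set.seed(seed)
  sc <- list(block = as.integer(scaffold$block),
             cond = as.integer(scaffold$condition == "other"),
             s1 = as.integer(scaffold$s1),
             action_left = as.integer(scaffold$action_left),
             pay0 = scaffold$pay0, pay1 = scaffold$pay1)
  kp <- if (is.null(agent$keypress_p)) 0.98 else agent$keypress_p
  mr <- if (is.null(agent$miss_rate)) 0 else agent$miss_rate
  out <- simulate_session_cpp(check_param_vector(agent$params), sc, dt,
                              config$rt_limit_ms / 1000,
                              config$fast_rt_cutoff_ms / 1000,
                              kp, mr, 1, TRUE, dest)
  data.frame(trial = scaffold$trial, block = scaffold$block,
             condition = scaffold$condition, s1 = scaffold$s1,
             a1 = out$a1,
             key = ifelse(is.na(out$key), NA_character_,
                          ifelse(out$key == 0, "left", "right")),
             rt_ms = out$rt * 1000, s2 = out$s2, keypress = out$keypress,
             reward = out$reward, valid = out$valid, vnet = out$vnet,
             stringsAsFactors = FALSE)
}

#' Simulate all sessions of a cohort
#'
#' Each agent is randomly assigned one of the two counterbalanced
#' scaffolds (50/50) and simulated with a per-agent seed derived from
#' `seed`.
#'
#' @param cohort List of agent specs.
#' @param pair A [generate_trial_sequence_pair()].
#' @param seed Integer seed.
#' @param ... Passed to [simulate_agent_session()].
#' @return List of session data frames, one per agent.
#' @export
simulate_cohort_sessions <- function(cohort, pair, seed = 1L, ...) {
  set.seed(seed)
  which_sc <- sample(c(TRUE, FALSE), length(cohort), replace = TRUE)
  agent_seeds <- sample.int(2^30, length(cohort))
  lapply(seq_along(cohort), function(i) {
    sc <- if (which_sc[i]) pair$scaffold_a else pair$scaffold_b
    simulate_agent_session(cohort[[i]], sc, seed = agent_seeds[i], ...)
  })
}

# per-block NLL of first-stage choices under a reference model
score_block_nll <- function(session, reference = c("state_mle", "fair_coin")) {
  reference <- match.arg(reference)
  sapply(sort(unique(session$block)), function(b) {
    sb <- session[session$block == b & !is.na(session$a1), , drop = FALSE]
    if (nrow(sb) == 0) return(0)
    if (reference == "fair_coin") return(nrow(sb) * log(2))
    nll <- 0
    for (s in unique(sb$s1)) {
      ch <- sb$a1[sb$s1 == s]
      p <- mean(ch == 0)
      ll <- sum(ch == 0) * log(max(p, 1e-12)) +
        sum(ch == 1) * log(max(1 - p, 1e-12))
      nll <- nll - ll
    }
    nll
  })
}

#' Random-agent negative log-likelihood null distribution
#'
#' Simulates agents choosing first-stage actions uniformly at random on the
#' scaffold and scores each block's choices under a reference model,
#' yielding a null distribution of per-block negative log-likelihoods for
#' random responding.  The default reference fits a per-block,
#' per-first-stage-state Bernoulli choice probability by maximum likelihood
#' before scoring (which places the thresholds slightly below
#' `60 * log(2)`, as the mild overfitting of the fitted reference model
#' implies); `"fair_coin"` scores at probability 0.5 exactly.  The
#' per-block cut-off is the `percentile`-th percentile of the null.
#'
#' @param scaffold Scaffold data frame.
#' @param n_agents Number of random agents (default 1000).
#' @param percentile Percentile defining the threshold (default 5).
#' @param reference `"state_mle"` (default) or `"fair_coin"`.
#' @param miss_rate Per-trial probability of a missing response.
#' @param seed Integer seed.
#' @return List with `thresholds` (one per block), `nll` (agents x blocks
#'   matrix), `reference`, `percentile`.
#' @export
random_agent_null <- function(scaffold, n_agents = 1000L, percentile = 5,
                              reference = c("state_mle", "fair_coin"),
                              miss_rate = 0, seed = 1L) {
  reference <- match.arg(reference)
  set.seed(seed)
  blocks <- sort(unique(scaffold$block))
  nll <- matrix(NA_real_, n_agents, length(blocks))
  for (i in seq_len(n_agents)) {
    a1 <- sample(0:1, nrow(scaffold), replace = TRUE)
    if (miss_rate > 0)
      a1[stats::runif(nrow(scaffold)) < miss_rate] <- NA_integer_
    ses <- data.frame(block = scaffold$block, s1 = scaffold$s1, a1 = a1)
    nll[i, ] <- score_block_nll(ses, reference)
  }
  thr <- apply(nll, 2, stats::quantile, probs = percentile / 100, names = FALSE)
  list(thresholds = thr, nll = nll, reference = reference,
       percentile = percentile, blocks = blocks)
}

#' Apply the exclusion pipeline to a cohort of sessions
#'
#' Two rules: (1) more than 20% invalid trials (missing responses or RTs
#' below the fast cutoff, out of all 240 trials); (2) random responding,
#' flagged when the per-block NLL under the reference model exceeds the
#' null threshold in every block of both the self and the other condition.
#'
#' @param sessions List of session data frames.
#' @param null Result of [random_agent_null()].
#' @param invalid_max Maximum tolerated invalid fraction (default 0.2).
#' @return List with `keep` (logical), `report` (data frame with per-agent
#'   `invalid_fraction`, `invalid_flag`, `random_flag`), and counts
#'   `n_excluded_invalid`, `n_excluded_random`.
#' @export
apply_exclusions <- function(sessions, null, invalid_max = 0.2) {
  rep_df <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    invalid_fraction <- mean(is.na(s$a1) | !s$valid)
    nll <- score_block_nll(s, null$reference)
    exceeds <- nll > null$thresholds
    cond_of_block <- tapply(as.character(s$condition), s$block,
                            function(x) x[1])[as.character(null$blocks)]
    random_flag <- all(exceeds[cond_of_block == "self"]) &&
      all(exceeds[cond_of_block == "other"])
    data.frame(id = i, invalid_fraction = invalid_fraction,
               invalid_flag = invalid_fraction > invalid_max,
               random_flag = random_flag)
  }))
  keep <- !(rep_df$invalid_flag | rep_df$random_flag)
  list(keep = keep, report = rep_df,
       n_excluded_invalid = sum(rep_df$invalid_flag),
       n_excluded_random = sum(rep_df$random_flag),
       thresholds = null$thresholds)
}

#' Write / read a session log as delimited text
#'
#' One row per trial with a header; round-trips through
#' [read_session()].
#'
#' @param session Session data frame.
#' @param path File path.
#' @export
write_session <- function(session, path) {
  utils::write.csv(session, path, row.names = FALSE)
}

#' @rdname write_session
#' @return `read_session` returns the session data frame.
#' @export
read_session <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s$keypress <- as.logical(s$keypress)
  s$valid <- as.logical(s$valid)
  s
}
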