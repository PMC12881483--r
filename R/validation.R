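#' Parameter recovery study
#'
#' Simulates each agent's session on one of the two pre-determined
#' scaffolds (assigned 50/50), refits it by MAP, and reports the Spearman
#' rank correlation between true and recovered values for each of the 14
#' parameters plus the Pearson intercorrelation matrix of the recovered
#' estimates.  Agents whose optimisation fails are flagged and dropped
#' from the correlations with a warning.
#'
#' @param cohort_cfg A [cohort_config()] (recovery mode for the classic
#'   uniform-range study).
#' @param opt An [optimizer_config()].
#' @param pair A [generate_trial_sequence_pair()]; generated from
#'   `cohort_cfg$seed` when missing.
#' @param fit Set `FALSE` to skip fitting and return the true values as
#'   the recovered ones (identity pipeline check).
#' @return List of class `recovery_result`: `true` and `recovered`
#'   (agents x 14 matrices), `rank_correlations` (named, length 14),
#'   `intercorrelations` (14 x 14), `failed` (indices).
#' @export
run_parameter_recovery <- function(cohort_cfg = cohort_config("recovery"),
                                   opt = optimizer_config(),
                                   pair = NULL, fit = TRUE) {
  if (is.null(pair))
    pair <- generate_trial_sequence_pair(seed = cohort_cfg$seed)
  cohort <- sample_cohort(cohort_cfg)
  sessions <- simulate_cohort_sessions(cohort, pair,
                                       seed = cohort_cfg$seed + 1L)
  true <- do.call(rbind, lapply(cohort, `[[`, "params"))
  if (!fit) {
    recovered <- true
    failed <- integer()
  } else {
    recovered <- matrix(NA_real_, length(cohort), 14,
                        dimnames = list(NULL, param_names()))
    failed <- integer()
    for (i in seq_along(cohort)) {
      oi <- opt
      oi$seed <- opt$seed + i * 1000L
      f <- tryCatch(fit_map(sessions[[i]], opt = oi), error = function(e) NULL)
      if (is.null(f)) failed <- c(failed, i) else recovered[i, ] <- f$par
    }
    if (length(failed) > 0)
      warning(length(failed), " agent(s) failed to fit and were excluded")
  }
  ok <- setdiff(seq_along(cohort), failed)
  rank_cor <- sapply(seq_len(14), function(j)
    stats::cor(true[ok, j], recovered[ok, j], method = "spearman"))
  names(rank_cor) <- param_names()
  intercor <- stats::cor(recovered[ok, , drop = FALSE])
  structure(list(true = true, recovered = recovered,
                 rank_correlations = rank_cor,
                 intercorrelations = intercor, failed = failed,
                 sessions = sessions, cohort = cohort, pair = pair),
            class = "recovery_result")
}

# per-agent summaries of one simulated cohort
cohort_summaries <- function(sessions) {
  total_reward <- sapply(sessions, function(s) sum(s$reward))
  rt_med <- sapply(sessions, function(s) stats::median(s$rt_ms, na.rm = TRUE))
  list(total_reward = total_reward, median_rt = rt_med)
}

# choice share of the higher-valued option and median RT by |net drift| bin
value_difference_profile <- function(sessions, n_bins = 5) {
  d <- do.call(rbind, lapply(sessions, function(s)
    s[!is.na(s$a1) & s$valid, c("vnet", "a1", "rt_ms")]))
  absv <- abs(d$vnet)
  chose_high <- ifelse(d$vnet > 0, d$a1 == 0,
                       ifelse(d$vnet < 0, d$a1 == 1, NA))
  bins <- cut(absv, stats::quantile(absv, seq(0, 1, length.out = n_bins + 1)),
              include.lowest = TRUE, labels = FALSE)
  data.frame(bin = seq_len(n_bins),
             mean_absv = tapply(absv, bins, mean),
             p_high = tapply(chose_high, bins, mean, na.rm = TRUE),
             median_rt = tapply(d$rt_ms, bins, stats::median))
}

#' Posterior predictive check
#'
#' Simulates `n_rep` replicate cohorts from per-agent (fitted) parameter
#' vectors and compares them with a reference cohort: (1) the correlation
#' between replicate-mean simulated per-agent rewards and the reference
#' per-agent rewards; (2) choice share of the higher-valued option and
#' median RT by absolute-value-difference bin; (3) optionally the stay
#' regression coefficients of each replicate, fitted with the fast
#' approximate posterior.
#'
#' @param params_list List of named 14-vectors, one per agent.
#' @param pair A [generate_trial_sequence_pair()].
#' @param reference_sessions Reference session list (same agents).
#' @param n_rep Number of replicates (study default 50).
#' @param seed Integer seed.
#' @param fit_regression Also run the stay regression per replicate.
#' @param keypress_p,miss_rate Response processes for the simulated agents.
#' @return List of class `ppc_result`: `reward_correlation` (per
#'   replicate), `value_profile` (pooled over replicates),
#'   `regression_means` (replicates x coefficients, if requested),
#'   `reference_regression`.
#' @export
posterior_predictive <- function(params_list, pair, reference_sessions,
                                 n_rep = 50L, seed = 1L,
                                 fit_regression = FALSE, keypress_p = 0.98,
                                 miss_rate = 0.02) {
  agents <- lapply(seq_along(params_list), function(i)
    list(id = i, params = params_list[[i]], keypress_p = keypress_p,
         miss_rate = miss_rate))
  ref_reward <- cohort_summaries(reference_sessions)$total_reward
  sim_rewards <- matrix(NA_real_, n_rep, length(agents))
  reg_means <- NULL
  all_sessions <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sessions <- simulate_cohort_sessions(agents, pair, seed = seed + 7919L * r)
    all_sessions[[r]] <- sessions
    sim_rewards[r, ] <- cohort_summaries(sessions)$total_reward
  }
  if (fit_regression) {
    reg_means <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      tab <- do.call(rbind, lapply(seq_along(all_sessions[[r]]), function(i)
        build_stay_table(all_sessions[[r]][[i]], id = i)))
      fit <- fit_stay_regression(tab, "base", sampler_config("laplace"))
      stats::setNames(fit$summary$mean, fit$summary$term)
    }))
  }
  reward_cor <- stats::cor(colMeans(sim_rewards), ref_reward)
  profile <- value_difference_profile(do.call(c, all_sessions))
  structure(list(reward_correlation = reward_cor,
                 per_agent_sim_reward = colMeans(sim_rewards),
                 value_profile = profile, regression_means = reg_means,
                 n_rep = n_rep),
            class = "ppc_result")
}

#' Mute self-other effects in a parameter vector
#'
#' Sets the named Other-condition quantities equal to Self: the
#' model-based-weight difference to zero (`mb_weight_only`), the Other
#' learning rate to the Self learning rate (`mf_learning_rate_only`), or
#' both.  Muting is idempotent.
#'
#' @param params Named 14-vector or a list of them.
#' @param what `"mb_weight_only"`, `"mf_learning_rate_only"`, `"both"`, or
#'   `"none"`.
#' @return Parameters with the named gaps removed.
#' @export
mute_params <- function(params, what = c("both", "mb_weight_only",
                                         "mf_learning_rate_only", "none")) {
  what <- match.arg(what)
  if (is.list(params)) return(lapply(params, mute_params, what = what))
  p <- check_param_vector(params)
  if (what %in% c("mb_weight_only", "both")) p[["diff_mb"]] <- 0
  if (what %in% c("mf_learning_rate_only", "both"))
    p[["alpha_other"]] <- p[["alpha_self"]]
  p
}

#' Selective parameter-muting simulation study
#'
#' For each requested muting configuration, simulates `n_rep` cohorts from
#' the (muted) parameter set, runs the stay regression on each with the
#' fast approximate posterior, and summarises the posterior-mean
#' coefficients.  Comparing the muted configurations with the unmuted
#' baseline shows which parameter gaps drive the condition-dependent
#' stay-probability signatures.
#'
#' @param params_list List of named 14-vectors (fitted or planted), with
#'   nonzero self-other gaps.
#' @param pair A [generate_trial_sequence_pair()].
#' @param configs Character vector of configurations to run.
#' @param n_rep Replicates per configuration (study default 50).
#' @param seed Integer seed.
#' @param keypress_p,miss_rate Response processes.
#' @return List of class `muting_result`: per configuration a matrix of
#'   per-replicate coefficient means, plus `coef_means` (configurations x
#'   coefficients).
#' @export
muting_study <- function(params_list, pair,
                         configs = c("none", "mb_weight_only",
                                     "mf_learning_rate_only", "both"),
                         n_rep = 50L, seed = 1L, keypress_p = 0.98,
                         miss_rate = 0.02) {
  res <- list()
  for (cfg in configs) {
    pl <- mute_params(params_list, what = cfg)
    agents <- lapply(seq_along(pl), function(i)
      list(id = i, params = pl[[i]], keypress_p = keypress_p,
           miss_rate = miss_rate))
    rows <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      sessions <- simulate_cohort_sessions(agents, pair,
                                           seed = seed + 7919L * r)
      tab <- do.call(rbind, lapply(seq_along(sessions), function(i)
        build_stay_table(sessions[[i]], id = i)))
      fit <- fit_stay_regression(tab, "base", sampler_config("laplace"))
      stats::setNames(fit$summary$mean, fit$summary$term)
    }))
    res[[cfg]] <- rows
  }
  coef_means <- do.call(rbind, lapply(res, colMeans))
  structure(list(replicates = res, coef_means = coef_means, n_rep = n_rep),
            class = "muting_result")
}
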