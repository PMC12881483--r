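#' Fit every agent of a cohort by MAP
#'
#' @param sessions List of session data frames.
#' @param opt An [optimizer_config()]; agent `i` uses seed
#'   `opt$seed + 1000 * i`.
#' @return Matrix (agents x 14) of MAP estimates.
#' @export
fit_cohort <- function(sessions, opt = optimizer_config()) {
  out <- matrix(NA_real_, length(sessions), 14,
                dimnames = list(NULL, param_names()))
  for (i in seq_along(sessions)) {
    oi <- opt
    oi$seed <- opt$seed + 1000L * i
    out[i, ] <- fit_map(sessions[[i]], opt = oi)$par
  }
  out
}

#' Self-Other parameter differences from a parameter matrix
#'
#' @param params Matrix (agents x 14) in [param_names()] order.
#' @return Data frame of Self minus Other differences for the seven
#'   condition-level parameters.
#' @export
param_differences <- function(params) {
  data.frame(beta_mb = -params[, "diff_mb"],
             beta_mf = -params[, "diff_mf"],
             alpha = params[, "alpha_self"] - params[, "alpha_other"],
             pi = params[, "pi_self"] - params[, "pi_other"],
             rho = params[, "rho_self"] - params[, "rho_other"],
             boundary = params[, "bound_self"] - params[, "bound_other"],
             ndt = params[, "ndt_self"] - params[, "ndt_other"])
}

#' End-to-end planted-effect study
#'
#' Runs the full pipeline on one synthetic cohort: sample agents with the
#' planted self-other effects, simulate their sessions, fit every agent by
#' MAP, run the stay regression, the mediation analysis (condition ->
#' non-decision time -> model-based weight) and the SVO moderation, and
#' report the key quantities with their signs.
#'
#' @param seed Integer seed driving every stage.
#' @param cohort_cfg A planted-mode [cohort_config()] (its `seed` is
#'   overridden by `seed`).
#' @param opt An [optimizer_config()].
#' @param n_boot Bootstrap iterations for the mediation stage.
#' @return List with `fits` (agents x 14), `regression` (stay_fit),
#'   `mediation`, `svo_mod`, `diffs`, `signs` (named logical/numeric
#'   summary of the three planted-effect signs), `cohort`, `sessions`.
#' @export
planted_cohort_study <- function(seed = 1L,
                                 cohort_cfg = cohort_config("planted"),
                                 opt = optimizer_config(),
                                 n_boot = 2000L) {
  cohort_cfg$seed <- as.integer(seed)
  pair <- generate_trial_sequence_pair(seed = seed + 11L)
  cohort <- sample_cohort(cohort_cfg)
  sessions <- simulate_cohort_sessions(cohort, pair, seed = seed + 23L)
  opt$seed <- as.integer(seed + 101L)
  fits <- fit_cohort(sessions, opt)
  svo <- sapply(cohort, `[[`, "svo")
  tab <- do.call(rbind, lapply(seq_along(sessions), function(i)
    build_stay_table(sessions[[i]], id = i, svo = svo[i])))
  reg <- fit_stay_regression(tab, "base", sampler_config("laplace"))
  diffs <- param_differences(fits)
  n <- nrow(fits)
  x <- rep(c(0.5, -0.5), each = n)
  m <- c(fits[, "ndt_self"], fits[, "ndt_other"])
  y <- c(fits[, "beta_mb_self"],
         fits[, "beta_mb_self"] + fits[, "diff_mb"])
  med <- mediation(x, m, y, n_boot = n_boot, seed = seed + 31L,
                   id = rep(seq_len(n), 2))
  svo_mod <- svo_moderation(diffs, svo)
  coef_po_so <- reg$summary$mean[reg$summary$term == "po:so"]
  signs <- c(po_selfother_positive = coef_po_so > 0,
             indirect_positive = med$indirect$est > 0,
             svo_moderation_negative = svo_mod$main$r < 0)
  list(fits = fits, regression = reg, mediation = med, svo_mod = svo_mod,
       diffs = diffs, signs = signs,
       values = c(po_selfother = coef_po_so,
                  indirect = med$indirect$est,
                  svo_r = svo_mod$main$r,
                  mean_gap_mb = mean(diffs$beta_mb),
                  mean_gap_ndt = mean(diffs$ndt)),
       cohort = cohort, sessions = sessions, pair = pair)
}
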