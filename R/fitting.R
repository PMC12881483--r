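#' Prior specification for MAP estimation
#'
#' Standard normal priors on the Self drift weights and both conditions'
#' stickiness parameters; `Normal(0, 0.5)` on the two Other-Self
#' differences; `Beta(2, 2)` on the learning rates; Gamma priors on the
#' boundary (`Gamma(1.5, 0.75)`) and non-decision time (`Gamma(0.8, 0.2)`).
#' The Gamma priors are interpreted as shape-scale by default (prior means
#' 1.125 and 0.16), which keeps the non-decision-time prior inside its
#' search box; a shape-rate reading is available via `gamma_param`.
#'
#' @param gamma_param `"scale"` (default) or `"rate"`.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(gamma_param = c("scale", "rate")) {
  gamma_param <- match.arg(gamma_param)
  structure(list(normal_sd = 1, diff_sd = 0.5,
                 alpha_shape = c(2, 2),
                 bound_gamma = c(1.5, 0.75), ndt_gamma = c(0.8, 0.2),
                 gamma_param = gamma_param),
            class = "prior_spec")
}

#' Box search space of the 14 parameters
#'
#' Drift weights and stickiness in `[-3, 3]`, the two differences in
#' `[-1, 1]`, learning rates in `[0.00001, 0.99999]`, boundary in
#' `[0.3, 3]`, non-decision time in `[0.001, 1]` seconds.
#'
#' @return 14 x 2 matrix (`lower`, `upper`) with [param_names()] rownames.
#' @export
search_space <- function() {
  lower <- c(-3, -3, -1, -1, 1e-5, 1e-5, -3, -3, -3, -3, 0.3, 0.3, 0.001, 0.001)
  upper <- c(3, 3, 1, 1, 0.99999, 0.99999, 3, 3, 3, 3, 3, 3, 1, 1)
  m <- cbind(lower = lower, upper = upper)
  rownames(m) <- param_names()
  m
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the fitting procedure: population of 200 candidate
#' solutions, 100 parents, 100 generations, 14 genes, 10 restarts from
#' different initial populations with the best restart retained.
#'
#' @param n_generations,n_parents,population_size,n_genes,n_restarts GA
#'   hyperparameters.
#' @param mutation_prob Per-gene mutation probability.
#' @param mutation_sd_frac Mutation SD as a fraction of each box width.
#' @param seed Base seed; restart `r` uses `seed + r`.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(n_generations = 100L, n_parents = 100L,
                             population_size = 200L, n_genes = 14L,
                             n_restarts = 10L, mutation_prob = 0.1,
                             mutation_sd_frac = 0.1, seed = 1L) {
  stopifnot(population_size >= n_parents, n_genes == 14L, n_restarts >= 1)
  structure(list(n_generations = as.integer(n_generations),
                 n_parents = as.integer(n_parents),
                 population_size = as.integer(population_size),
                 n_genes = as.integer(n_genes),
                 n_restarts = as.integer(n_restarts),
                 mutation_prob = mutation_prob,
                 mutation_sd_frac = mutation_sd_frac,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Summed log-prior density of a 14-parameter vector
#'
#' @param params 14-parameter vector or matrix (rows = candidates).
#' @param priors A [prior_spec()].
#' @return Numeric vector of log-prior densities; `-Inf` outside support.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  if (is.null(dim(params))) params <- matrix(check_param_vector(params), 1)
  g <- function(x, par) {
    if (priors$gamma_param == "scale")
      stats::dgamma(x, shape = par[1], scale = par[2], log = TRUE)
    else
      stats::dgamma(x, shape = par[1], rate = par[2], log = TRUE)
  }
  lp <- stats::dnorm(params[, 1], 0, priors$normal_sd, log = TRUE) +
    stats::dnorm(params[, 2], 0, priors$normal_sd, log = TRUE) +
    stats::dnorm(params[, 3], 0, priors$diff_sd, log = TRUE) +
    stats::dnorm(params[, 4], 0, priors$diff_sd, log = TRUE) +
    stats::dbeta(params[, 5], priors$alpha_shape[1], priors$alpha_shape[2], log = TRUE) +
    stats::dbeta(params[, 6], priors$alpha_shape[1], priors$alpha_shape[2], log = TRUE) +
    stats::dnorm(params[, 7], 0, priors$normal_sd, log = TRUE) +
    stats::dnorm(params[, 8], 0, priors$normal_sd, log = TRUE) +
    stats::dnorm(params[, 9], 0, priors$normal_sd, log = TRUE) +
    stats::dnorm(params[, 10], 0, priors$normal_sd, log = TRUE) +
    g(params[, 11], priors$bound_gamma) + g(params[, 12], priors$bound_gamma) +
    g(params[, 13], priors$ndt_gamma) + g(params[, 14], priors$ndt_gamma)
  lp[!is.finite(lp)] <- -Inf
  lp
}

#' Log-posterior: session log-likelihood plus log-prior
#'
#' @param params 14-parameter vector or candidate matrix.
#' @param session Session data frame (may have zero rows: the value is then
#'   the summed log-prior alone).
#' @param dest Transition matrix.
#' @param priors A [prior_spec()].
#' @param ... Passed to [session_loglik()].
#' @return Numeric vector of log-posterior values.
#' @export
log_posterior <- function(params, session, dest = make_transition_structure(),
                          priors = prior_spec(), ...) {
  session_loglik(params, session, dest, ...) + log_prior(params, priors)
}

# clip candidate matrix into the box
clip_box <- function(x, space) {
  for (j in seq_len(ncol(x)))
    x[, j] <- pmin(pmax(x[, j], space[j, 1]), space[j, 2])
  x
}

#' MAP estimation by a multi-start genetic algorithm
#'
#' Elitist steady-state GA: each generation keeps the `n_parents` best
#' candidates and refills the population with offspring made by uniform
#' crossover of random parent pairs plus per-gene Gaussian mutation
#' (probability `mutation_prob`, SD `mutation_sd_frac` of the box width),
#' clipped to the search box.  The whole procedure is restarted
#' `n_restarts` times from different seeded initial populations and the
#' restart with the highest log-posterior wins.  Identical seeds reproduce
#' identical estimates.
#'
#' @param session Session data frame.
#' @param dest Transition matrix.
#' @param priors A [prior_spec()].
#' @param space Box constraints from [search_space()].
#' @param opt An [optimizer_config()].
#' @return List of class `map_fit`: `par` (named 14-vector), `logpost`,
#'   `restart_best` (per-restart best values), `selected_restart`, and
#'   `trace` (best-so-far log-posterior per generation of the winning
#'   restart, non-decreasing by construction).
#' @export
fit_map <- function(session, dest = make_transition_structure(),
                    priors = prior_spec(), space = search_space(),
                    opt = optimizer_config()) {
  arr <- if (nrow(session) > 0) session_to_arrays(session, dest) else NULL
  fitness <- function(pop) {
    ll <- if (is.null(arr)) 0 else session_loglik_cpp(pop, arr, 1e-7, TRUE, 1)
    lp <- ll + log_prior(pop, priors)
    lp[!is.finite(lp)] <- -1e12
    lp
  }
  width <- space[, 2] - space[, 1]
  best <- vector("list", opt$n_restarts)
  restart_best <- numeric(opt$n_restarts)
  traces <- vector("list", opt$n_restarts)
  for (r in seq_len(opt$n_restarts)) {
    set.seed(opt$seed + r)
    pop <- sapply(seq_len(14), function(j)
      stats::runif(opt$population_size, space[j, 1], space[j, 2]))
    fit <- fitness(pop)
    trace <- numeric(opt$n_generations)
    n_off <- opt$population_size - opt$n_parents
    for (gen in seq_len(opt$n_generations)) {
      ord <- order(fit, decreasing = TRUE)
      parents <- pop[ord[seq_len(opt$n_parents)], , drop = FALSE]
      pfit <- fit[ord[seq_len(opt$n_parents)]]
      i1 <- sample.int(opt$n_parents, n_off, replace = TRUE)
      i2 <- sample.int(opt$n_parents, n_off, replace = TRUE)
      mask <- matrix(stats::runif(n_off * 14) < 0.5, n_off, 14)
      off <- ifelse(mask, parents[i1, , drop = FALSE],
                    parents[i2, , drop = FALSE])
      mut <- matrix(stats::runif(n_off * 14) < opt$mutation_prob, n_off, 14)
      noise <- matrix(stats::rnorm(n_off * 14), n_off, 14) *
        rep(width * opt$mutation_sd_frac, each = n_off)
      off <- clip_box(off + mut * noise, space)
      ofit <- fitness(off)
      pop <- rbind(parents, off)
      fit <- c(pfit, ofit)
      trace[gen] <- max(fit)
    }
    i <- which.max(fit)
    best[[r]] <- pop[i, ]
    restart_best[r] <- fit[i]
    traces[[r]] <- cummax(trace)
  }
  if (all(!is.finite(restart_best)))
    stop("all restarts failed to evaluate the posterior")
  sel <- which.max(restart_best)
  par <- best[[sel]]
  names(par) <- param_names()
  structure(list(par = par, logpost = restart_best[sel],
                 restart_best = restart_best, selected_restart = sel,
                 trace = traces[[sel]], opt = opt),
            class = "map_fit")
}
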