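#' Build the stay-probability regression table
#'
#' For each valid trial with a valid predecessor in the same block, one row
#' is produced: `stay = 1` iff the trial revisits the previous trial's
#' second-stage state, `prev_outcome` is the previous trial's reward,
#' `first_stage_same = 1` iff the same pair of spaceships was encountered,
#' and the recipient condition is effect coded (self +0.5, other -0.5).
#' Rows never span block boundaries (a recipient switch breaks the
#' trial-pair logic) and a trial whose predecessor is invalid contributes
#' no row.
#'
#' @param session Session data frame.
#' @param id Participant identifier attached to every row.
#' @param svo Optional SVO angle (degrees) for this participant; z-scoring
#'   happens across participants in [fit_stay_regression()].
#' @return Data frame with columns `id`, `stay`, `prev_outcome`,
#'   `first_stage_same`, `self_other`, `svo`.
#' @export
build_stay_table <- function(session, id = 1L, svo = NA_real_) {
  rows <- lapply(sort(unique(session$block)), function(b) {
    sb <- session[session$block == b, , drop = FALSE]
    sb <- sb[!is.na(sb$a1) & sb$valid, , drop = FALSE]
    if (nrow(sb) < 2) return(NULL)
    # consecutive valid trials only: predecessor must be the immediately
    # preceding trial in the block
    cur <- sb[-1, , drop = FALSE]
    prv <- sb[-nrow(sb), , drop = FALSE]
    adjacent <- cur$trial == prv$trial + 1
    cur <- cur[adjacent, , drop = FALSE]
    prv <- prv[adjacent, , drop = FALSE]
    if (nrow(cur) == 0) return(NULL)
    data.frame(id = id,
               stay = as.integer(cur$s2 == prv$s2),
               prev_outcome = prv$reward,
               first_stage_same = as.integer(cur$s1 == prv$s1),
               self_other = ifelse(cur$condition == "self", 0.5, -0.5),
               svo = svo)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(), stay = integer(),
                      prev_outcome = numeric(), first_stage_same = integer(),
                      self_other = numeric(), svo = numeric())
  out
}

#' Sampler configuration for the stay regressions
#'
#' @param method `"laplace"` for the fast Gaussian (Laplace) posterior
#'   approximation built on penalised-likelihood mixed-model fits, used
#'   inside simulation loops; `"mcmc"` for full Markov chain Monte Carlo
#'   with JAGS.
#' @param chains,iterations,warmup MCMC settings (defaults 4 chains of
#'   2500 iterations, 500 warm-up, retaining 8000 draws).
#' @param seed Integer seed.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(method = c("laplace", "mcmc"), chains = 4L,
                           iterations = 2500L, warmup = 500L, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "sampler_config")
}

stay_model_matrix <- function(table, with_svo) {
  po <- as.numeric(scale(table$prev_outcome))
  if (stats::sd(table$prev_outcome) == 0) po <- table$prev_outcome * 0
  d <- data.frame(stay = table$stay, po = po,
                  fs = table$first_stage_same, so = table$self_other,
                  id = factor(table$id))
  if (with_svo) {
    svo_by_id <- tapply(table$svo, table$id, function(x) x[1])
    z <- as.numeric(scale(svo_by_id))
    d$svo <- z[match(as.character(d$id), names(svo_by_id))]
  }
  d
}

jags_stay_model <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- inprod(X[i, ], beta) + inprod(Z[i, ], b[id[i], ])
    y[i] ~ dbern(p[i])
  }
  for (k in 1:P) { beta[k] ~ dnorm(0, 0.04) }
  for (j in 1:J) {
    for (k in 1:Q) { b[j, k] ~ dnorm(0, tau[k]) }
  }
  for (k in 1:Q) {
    sigma[k] ~ dt(0, 0.16, 1) T(0, )
    tau[k] <- pow(sigma[k], -2)
  }
}"

#' Hierarchical Bayesian logistic regression of stay probabilities
#'
#' Fits `stay ~ prev_outcome * first_stage * self_other` (variant
#' `"base"`) or the same crossed with z-scored SVO (variant `"with_svo"`),
#' with the full `prev_outcome * first_stage * self_other` random-slope
#' structure per participant.  Previous outcome is standardised in the
#' model matrix.  `method = "mcmc"` samples the posterior with JAGS
#' (weakly informative priors: Normal(0, 5) on coefficients, half-Cauchy
#' (2.5) on random-effect SDs); `method = "laplace"` approximates the
#' posterior by a Gaussian centred on the penalised-likelihood estimate of
#' the corresponding `lme4` model with independent random slopes, which is
#' the fast route used inside posterior-predictive and muting loops.
#'
#' @param table Stay table from [build_stay_table()] (rows from all
#'   participants bound together).
#' @param variant `"base"` or `"with_svo"`.
#' @param sampler A [sampler_config()].
#' @return List of class `stay_fit`: `summary` (data frame with posterior
#'   `mean`, `hdi_lower`, `hdi_upper`, `iqr_lower`, `iqr_upper`,
#'   `significant` per coefficient), `participant_coefficients` (posterior
#'   expectations of per-participant slopes), `method`, `diagnostics`.
#' @export
fit_stay_regression <- function(table, variant = c("base", "with_svo"),
                                sampler = sampler_config()) {
  variant <- match.arg(variant)
  if (nrow(table) == 0) stop("empty stay table")
  with_svo <- variant == "with_svo"
  if (with_svo && all(is.na(table$svo)))
    stop("variant 'with_svo' requires svo values")
  d <- stay_model_matrix(table, with_svo)
  fixed_f <- if (with_svo) ~ po * fs * so * svo else ~ po * fs * so
  X <- stats::model.matrix(fixed_f, d)
  Z <- stats::model.matrix(~ po * fs * so, d)
  if (sampler$method == "laplace") {
    f <- if (with_svo)
      stay ~ po * fs * so * svo + (po * fs * so || id)
    else
      stay ~ po * fs * so + (po * fs * so || id)
    fit <- lme4::glmer(f, data = d, family = stats::binomial, nAGQ = 0L,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    summ <- data.frame(term = names(est), mean = unname(est),
                       hdi_lower = unname(est - 1.96 * se),
                       hdi_upper = unname(est + 1.96 * se),
                       iqr_lower = unname(est + stats::qnorm(0.25) * se),
                       iqr_upper = unname(est + stats::qnorm(0.75) * se))
    re <- lme4::ranef(fit)$id
    ids <- rownames(re)
    pc <- matrix(0, length(ids), ncol(Z),
                 dimnames = list(ids, colnames(Z)))
    for (nm in colnames(Z)) {
      pc[, nm] <- est[[nm]] + if (nm %in% colnames(re)) re[[nm]] else 0
    }
    diagnostics <- list(converged = length(fit@optinfo$conv$lme4) == 0)
  } else {
    if (!requireNamespace("rjags", quietly = TRUE))
      stop("rjags is required for method = 'mcmc'")
    set.seed(sampler$seed)
    id_idx <- as.integer(d$id)
    data_j <- list(y = d$stay, X = X, Z = Z, id = id_idx, N = nrow(X),
                   P = ncol(X), Q = ncol(Z), J = max(id_idx))
    inits <- lapply(seq_len(sampler$chains), function(k)
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = sampler$seed + k))
    jm <- rjags::jags.model(textConnection(jags_stay_model), data = data_j,
                            inits = inits, n.chains = sampler$chains,
                            n.adapt = max(sampler$warmup, 100), quiet = TRUE)
    stats::update(jm, sampler$warmup, progress.bar = "none")
    draws <- rjags::coda.samples(jm, c("beta", "b"),
                                 n.iter = sampler$iterations - sampler$warmup,
                                 progress.bar = "none")
    m <- as.matrix(draws)
    beta_cols <- grep("^beta\\[", colnames(m))
    bm <- m[, beta_cols, drop = FALSE]
    hdi <- coda::HPDinterval(coda::as.mcmc(bm), prob = 0.95)
    iqr <- t(apply(bm, 2, stats::quantile, probs = c(0.25, 0.75)))
    summ <- data.frame(term = colnames(X), mean = colMeans(bm),
                       hdi_lower = hdi[, 1], hdi_upper = hdi[, 2],
                       iqr_lower = iqr[, 1], iqr_upper = iqr[, 2])
    ids <- levels(d$id)
    pc <- matrix(0, length(ids), ncol(Z), dimnames = list(ids, colnames(Z)))
    for (k in seq_len(ncol(Z))) {
      for (j in seq_along(ids)) {
        bj <- m[, sprintf("b[%d,%d]", j, k)]
        pc[j, k] <- mean(bm[, k]) + mean(bj)
      }
    }
    ess <- tryCatch(coda::effectiveSize(coda::as.mcmc(bm)),
                    error = function(e) rep(NA_real_, ncol(bm)))
    gel <- tryCatch(coda::gelman.diag(draws[, beta_cols, drop = FALSE],
                                      multivariate = FALSE)$psrf[, 1],
                    error = function(e) rep(NA_real_, length(beta_cols)))
    diagnostics <- list(ess = ess, rhat = gel)
    if (any(is.finite(gel) & gel > 1.2))
      warning("MCMC convergence diagnostics indicate Rhat > 1.2; ",
              "inspect diagnostics before interpreting the fit")
  }
  summ$significant <- summ$hdi_lower > 0 | summ$hdi_upper < 0
  rownames(summ) <- NULL
  structure(list(summary = summ, participant_coefficients = pc,
                 method = sampler$method, variant = variant,
                 diagnostics = diagnostics),
            class = "stay_fit")
}

#' Descriptive stay probabilities by binarised previous outcome
#'
#' Summary used for the classic four-bar visualisation of the two
#' learning signatures: mean stay probability split by whether the
#' previous reward exceeded 5 and by first-stage-state repetition
#' (optionally also by condition).  The binarisation is for display only;
#' the regressions use the continuous previous outcome.
#'
#' @param table Stay table from [build_stay_table()].
#' @param by_condition Also split by the self/other condition.
#' @return Data frame with `prev_high`, `first_stage_same`, (optionally
#'   `condition`,) `stay_prob` and `n`.
#' @export
stay_visual_summary <- function(table, by_condition = FALSE) {
  f <- list(prev_high = table$prev_outcome > 5,
            first_stage_same = table$first_stage_same)
  if (by_condition)
    f$condition <- ifelse(table$self_other > 0, "self", "other")
  agg <- stats::aggregate(table$stay, f, function(x) c(mean(x), length(x)))
  out <- agg[setdiff(names(agg), "x")]
  out$stay_prob <- agg$x[, 1]
  out$n <- as.integer(agg$x[, 2])
  out
}

#' Paired t-test with effect size
#'
#' Standard paired t statistics with Cohen's d computed as the mean
#' difference over the SD of the differences.  Identical vectors (all
#' differences zero) return `t = 0`, `d = 0`, `p = 1`; a nonzero constant
#' difference (zero variance but a real effect) is an error.
#'
#' @param self_values,other_values Equal-length paired vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `t`, `dof`, `p`, `ci` (95% CI of the mean
#'   difference), `d`, `mean_diff`.
#' @export
paired_t <- function(self_values, other_values,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(self_values) == length(other_values),
            length(self_values) >= 2)
  diffs <- self_values - other_values
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0))
      return(list(t = 0, dof = length(diffs) - 1, p = 1, ci = c(0, 0),
                  d = 0, mean_diff = 0))
    stop("zero variance of differences")
  }
  tt <- stats::t.test(self_values, other_values, paired = TRUE,
                      alternative = alternative)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int),
       d = mean(diffs) / stats::sd(diffs), mean_diff = mean(diffs))
}

#' Power of the paired t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param d Cohen's d for the paired differences.
#' @param n Number of pairs.
#' @param alpha Significance level.
#' @param one_sided One-sided test (default TRUE).
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(d, n, alpha = 0.05, one_sided = TRUE) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (one_sided) {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  }
}
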