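#' Pearson correlation with confidence interval
#'
#' @param x,y Aligned numeric vectors.
#' @return List with `r`, `ci` (95%), `p`, `n`.
#' @keywords internal
cor_ci <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), ci = unname(ct$conf.int), p = ct$p.value,
       n = sum(ok))
}

#' Correlations between behavioural signatures and parameter differences
#'
#' Pearson correlations (with 95% CIs and p-values) between each
#' participant-level regression coefficient (the prosocial model-based
#' signature `prev_outcome x self_other` and the model-free signature
#' `prev_outcome x first_stage x self_other`) and each Self-Other
#' parameter difference.
#'
#' @param participant_coefficients Matrix (participants x terms), e.g.
#'   from [fit_stay_regression()]; column names identify the terms.
#' @param param_differences Matrix or data frame (participants x
#'   parameters) of Self-Other differences, aligned by row.
#' @return Data frame with one row per (signature, parameter) pair:
#'   `signature`, `parameter`, `r`, `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
signature_parameter_correlations <- function(participant_coefficients,
                                             param_differences) {
  if (nrow(participant_coefficients) < 3) stop("need at least 3 participants")
  stopifnot(nrow(participant_coefficients) == nrow(param_differences))
  param_differences <- as.data.frame(param_differences)
  rows <- list()
  for (sg in colnames(participant_coefficients)) {
    for (pr in colnames(param_differences)) {
      cc <- cor_ci(participant_coefficients[, sg], param_differences[[pr]])
      rows[[length(rows) + 1]] <-
        data.frame(signature = sg, parameter = pr, r = cc$r,
                   ci_lower = cc$ci[1], ci_upper = cc$ci[2], p = cc$p,
                   n = cc$n)
    }
  }
  do.call(rbind, rows)
}

#' SVO moderation of the model-based-weight gap
#'
#' Pearson correlation between the Self-Other model-based-weight
#' difference and SVO (degrees), plus a specificity scan over all
#' remaining parameter differences.
#'
#' @param param_differences Data frame of Self-Other differences with a
#'   column `beta_mb` (remaining columns are scanned).
#' @param svo SVO angles, aligned by row.
#' @return List with `main` (`r`, `ci`, `p`, `n` for the model-based
#'   weight) and `scan` (data frame over the other parameters).
#' @export
svo_moderation <- function(param_differences, svo) {
  param_differences <- as.data.frame(param_differences)
  stopifnot("beta_mb" %in% colnames(param_differences),
            nrow(param_differences) == length(svo))
  main <- cor_ci(param_differences$beta_mb, svo)
  others <- setdiff(colnames(param_differences), "beta_mb")
  scan <- do.call(rbind, lapply(others, function(pr) {
    cc <- cor_ci(param_differences[[pr]], svo)
    data.frame(parameter = pr, r = cc$r, ci_lower = cc$ci[1],
               ci_upper = cc$ci[2], p = cc$p, n = cc$n)
  }))
  list(main = main, scan = scan)
}

#' Bootstrap mediation analysis
#'
#' Simple (single-mediator) mediation on long-format data with two rows
#' per participant (one per condition, `x` effect coded): path `a` from
#' `x` to the mediator, path `b` from the mediator to the outcome
#' controlling `x`, total effect `c`, direct effect `c'`, and indirect
#' effect `a * b`, all estimated by linear regression.  Confidence
#' intervals come from a percentile bootstrap over `n_boot` resamples;
#' rows are resampled by default, or whole participants when `id` is
#' given and `resample = "participant"`.  Optional covariates (e.g. SVO)
#' are partialled from every path.
#'
#' @param x Condition code (+0.5 / -0.5), length 2 * participants.
#' @param m Mediator (e.g. non-decision time).
#' @param y Outcome (e.g. model-based weight).
#' @param covariates Optional data frame / matrix of covariates.
#' @param n_boot Bootstrap iterations (study default 10000).
#' @param seed Integer seed.
#' @param id Participant identifiers (required for participant
#'   resampling).
#' @param resample `"row"` (default) or `"participant"`.
#' @param conf Confidence level.
#' @return List of class `mediation_result` with `a`, `b`, `c`, `c_prime`,
#'   `indirect` (each a list with `est` and `ci`) and `n_boot`.
#' @export
mediation <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                      seed = 1L, id = NULL,
                      resample = c("row", "participant"), conf = 0.95) {
  resample <- match.arg(resample)
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (stats::sd(m) == 0 || stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("degenerate variance in x, m or y")
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  paths <- function(idx) {
    xi <- x[idx]; mi <- m[idx]; yi <- y[idx]
    ci <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    Xa <- if (is.null(ci)) cbind(1, xi) else cbind(1, xi, ci)
    Xb <- if (is.null(ci)) cbind(1, xi, mi) else cbind(1, xi, mi, ci)
    a <- stats::lm.fit(Xa, mi)$coefficients[2]
    bc <- stats::lm.fit(Xb, yi)$coefficients
    ctot <- stats::lm.fit(Xa, yi)$coefficients[2]
    c(a = unname(a), b = unname(bc[3]), c = unname(ctot),
      c_prime = unname(bc[2]), indirect = unname(a * bc[3]))
  }
  est <- paths(seq_len(n))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 5)
  if (resample == "participant") {
    if (is.null(id)) stop("participant resampling requires id")
    split_idx <- split(seq_len(n), id)
    for (b in seq_len(n_boot)) {
      pick <- sample(length(split_idx), replace = TRUE)
      idx <- unlist(split_idx[pick], use.names = FALSE)
      boot[b, ] <- paths(idx)
    }
  } else {
    for (b in seq_len(n_boot)) {
      boot[b, ] <- paths(sample.int(n, replace = TRUE))
    }
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  out <- lapply(1:5, function(j)
    list(est = unname(est[j]),
         ci = unname(stats::quantile(boot[, j], probs, na.rm = TRUE))))
  names(out) <- c("a", "b", "c", "c_prime", "indirect")
  out$n_boot <- n_boot
  class(out) <- "mediation_result"
  out
}

#' Partial correlation controlling a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariate(s); the p-value and CI use n - k - 2 degrees of
#' freedom (k covariates).  A constant covariate falls back to the plain
#' correlation with a warning.
#'
#' @param x,y Aligned numeric vectors.
#' @param covar Covariate vector or matrix.
#' @return List with `r`, `ci` (95%), `p`, `n`.
#' @export
partial_correlation <- function(x, y, covar) {
  covar <- as.matrix(covar)
  n <- length(x)
  stopifnot(length(y) == n, nrow(covar) == n, n >= 4)
  if (all(apply(covar, 2, stats::sd) == 0)) {
    warning("constant covariate; returning plain correlation")
    return(cor_ci(x, y))
  }
  X <- cbind(1, covar)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  # a variable fully explained by the covariate leaves only numerical
  # noise in its residuals: the partial correlation is 0 by definition
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1)) {
    r <- 0
  } else {
    r <- stats::cor(rx, ry)
  }
  k <- ncol(covar)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(r)
  se <- 1 / sqrt(n - k - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, ci = ci, p = p, n = n)
}
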