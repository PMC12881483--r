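#' Canonical order of the 14 free RLDDM parameters
#'
#' The model has 7 parameters per recipient condition.  The Other-condition
#' drift weights are parameterised as Self + difference, so the 14 free
#' quantities are the Self weights, the two Other-Self differences, and the
#' remaining five parameters free per condition.
#'
#' @return Character vector of the 14 parameter names, in the order used by
#'   every parameter vector and matrix in the package.
#' @export
param_names <- function() {
  c("beta_mb_self", "beta_mf_self", "diff_mb", "diff_mf",
    "alpha_self", "alpha_other", "pi_self", "pi_other",
    "rho_self", "rho_other", "bound_self", "bound_other",
    "ndt_self", "ndt_other")
}

#' Condition-level RLDDM parameters
#'
#' The 7 parameters governing one recipient condition, plus the fixed
#' quantities: eligibility trace `lambda = 1`, unbiased start point
#' `z = boundary / 2`, diffusion noise `sigma = 1`.
#'
#' @param beta_mb,beta_mf Unbounded drift weights on model-based and
#'   model-free values.
#' @param alpha Model-free learning rate in `[0, 1]`.
#' @param pi Choice stickiness (same spaceship as previous trial).
#' @param rho Response stickiness (same key as previous trial).
#' @param boundary Decision boundary separation, > 0.
#' @param ndt Non-decision time in seconds, > 0.
#' @return A list of class `condition_params`.
#' @export
condition_params <- function(beta_mb = 0, beta_mf = 0, alpha = 0.5, pi = 0,
                             rho = 0, boundary = 1.5, ndt = 0.3) {
  stopifnot(alpha >= 0, alpha <= 1, boundary > 0, ndt > 0)
  structure(list(beta_mb = beta_mb, beta_mf = beta_mf, alpha = alpha,
                 pi = pi, rho = rho, boundary = boundary, ndt = ndt,
                 lambda = 1, z_rel = 0.5, sigma = 1),
            class = "condition_params")
}

#' Assemble a participant's 14-parameter vector
#'
#' @param self A `condition_params` for the Self condition.
#' @param diff_mb,diff_mf Other-Self differences in the drift weights.
#' @param other_alpha,other_pi,other_rho,other_boundary,other_ndt The five
#'   Other-condition parameters that are free (not difference-coded).
#' @return Named numeric vector of length 14 in [param_names()] order.
#' @export
participant_params <- function(self = condition_params(), diff_mb = 0,
                               diff_mf = 0, other_alpha = self$alpha,
                               other_pi = self$pi, other_rho = self$rho,
                               other_boundary = self$boundary,
                               other_ndt = self$ndt) {
  p <- c(self$beta_mb, self$beta_mf, diff_mb, diff_mf,
         self$alpha, other_alpha, self$pi, other_pi,
         self$rho, other_rho, self$boundary, other_boundary,
         self$ndt, other_ndt)
  names(p) <- param_names()
  p
}

#' Expand a 14-parameter vector into per-condition parameters
#'
#' The Other-condition drift weights are derived, never stored:
#' `beta_mb(Other) = beta_mb(Self) + diff_mb` and likewise for the
#' model-free weight.
#'
#' @param params Named numeric vector in [param_names()] order.
#' @return List with `self` and `other`, each a [condition_params()].
#' @export
expand_condition_params <- function(params) {
  params <- check_param_vector(params)
  list(self = condition_params(beta_mb = params[["beta_mb_self"]],
                               beta_mf = params[["beta_mf_self"]],
                               alpha = params[["alpha_self"]],
                               pi = params[["pi_self"]],
                               rho = params[["rho_self"]],
                               boundary = params[["bound_self"]],
                               ndt = params[["ndt_self"]]),
       other = condition_params(beta_mb = params[["beta_mb_self"]] + params[["diff_mb"]],
                                beta_mf = params[["beta_mf_self"]] + params[["diff_mf"]],
                                alpha = params[["alpha_other"]],
                                pi = params[["pi_other"]],
                                rho = params[["rho_other"]],
                                boundary = params[["bound_other"]],
                                ndt = params[["ndt_other"]]))
}

# coerce/validate a 14-vector; reorders by name when names are present
check_param_vector <- function(params) {
  if (length(params) != 14)
    stop("expected 14 parameters, got ", length(params))
  if (!is.null(names(params)) && all(param_names() %in% names(params)))
    params <- params[param_names()]
  else
    names(params) <- param_names()
  params
}
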