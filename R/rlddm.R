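#' Initialise the hybrid learner state
#'
#' Model-free values start at 4.5 (the average of the minimum and maximum
#' outcomes) for the second-stage states; first-stage values are also
#' initialised at 4.5, which makes the initial first-stage prediction error
#' zero.  Model-based values are never stored: they are derived on demand
#' from the second-stage values through the transition structure.
#'
#' @param q_init Initial value (default 4.5).
#' @return A list of class `learner_state` with `q1` (2 x 2 matrix, state x
#'   action) and `q2` (length-2 vector), plus the latest prediction errors
#'   `delta1`, `delta2` (NA before any update).
#' @export
learner_state <- function(q_init = 4.5) {
  structure(list(q1 = matrix(q_init, 2, 2,
                             dimnames = list(c("s0", "s1"), c("a0", "a1"))),
                 q2 = c(4.5, 4.5) * 0 + q_init,
                 delta1 = NA_real_, delta2 = NA_real_),
            class = "learner_state")
}

#' Model-free temporal-difference update
#'
#' Computes the two reward prediction errors from pre-update values,
#' `delta1 = Q_MF(s2) - Q_MF(s1, a1)` and `delta2 = r - Q_MF(s2)`, then
#' updates the visited entries only:
#' `Q_MF(s1, a1) += alpha * delta1 + alpha * lambda * delta2` and
#' `Q_MF(s2) += alpha * delta2`.  With `lambda = 1` the chained first-stage
#' update is algebraically `alpha * (r - Q_MF(s1, a1))`.
#'
#' @param state A [learner_state()].
#' @param s1,a1,s2 0-based visited state/action indices.
#' @param reward Registered reward.
#' @param alpha Learning rate in `[0, 1]`.
#' @param lambda_trace Eligibility trace (fixed at 1 in the model).
#' @return The updated `learner_state`.
#' @export
mf_update <- function(state, s1, a1, s2, reward, alpha, lambda_trace = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  d1 <- state$q2[s2 + 1] - state$q1[s1 + 1, a1 + 1]
  d2 <- reward - state$q2[s2 + 1]
  state$q1[s1 + 1, a1 + 1] <- state$q1[s1 + 1, a1 + 1] +
    alpha * d1 + alpha * lambda_trace * d2
  state$q2[s2 + 1] <- state$q2[s2 + 1] + alpha * d2
  state$delta1 <- d1
  state$delta2 <- d2
  state
}

#' Model-based first-stage values
#'
#' `Q_MB(s1, a1) = sum_{s2} T(s2 | s1, a1) * Q_MB(s2)`, where the
#' second-stage model-based values equal the model-free ones (both are the
#' immediate reward estimate).  Under the deterministic transition structure
#' this reads out the stage-2 value of each action's destination planet.
#'
#' @param state A [learner_state()].
#' @param dest Transition matrix from [make_transition_structure()].
#' @return 2 x 2 matrix of model-based values (state x action).
#' @export
mb_values <- function(state, dest = make_transition_structure()) {
  q <- matrix(NA_real_, 2, 2, dimnames = dimnames(dest))
  for (s in 1:2) for (a in 1:2) q[s, a] <- state$q2[dest[s, a] + 1]
  q
}

#' Per-action drift inputs and net drift rate
#'
#' The drift for each first-stage action is the four-term sum
#' `v(a) = beta_mb * Q_MB(s1, a) + beta_mf * Q_MF(s1, a) + pi * ch(a) +
#' rho * resp(a)`.  `ch(a) = 1` when `a` is the same spaceship chosen on the
#' previous trial (only possible when the first-stage state repeats, since
#' different states show different spaceship pairs); `resp(a) = 1` when the
#' key mapped to `a` on the current trial matches the previous keypress.
#' The net drift is `v(action 0) - v(action 1)`, with action 0 mapped to the
#' upper boundary.
#'
#' @param state A [learner_state()].
#' @param s1 Current 0-based first-stage state.
#' @param params A [condition_params()].
#' @param dest Transition matrix.
#' @param prev Previous-trial choice info: list with `state`, `action`,
#'   `key` (0 = left, 1 = right), or `NULL` on a block's first trial.
#' @param key_action0 Key (0/1) assigned to action 0 on the current trial.
#' @return List with per-action `v`, indicator vectors `ch`, `resp`, and
#'   `net` (= `v[1] - v[2]`).
#' @export
drift_rate <- function(state, s1, params, dest = make_transition_structure(),
                       prev = NULL, key_action0 = 0L) {
  qmb <- mb_values(state, dest)[s1 + 1, ]
  qmf <- state$q1[s1 + 1, ]
  ch <- resp <- c(0, 0)
  if (!is.null(prev) && !is.null(prev$action) && !is.na(prev$action)) {
    if (identical(prev$state, s1)) ch[prev$action + 1] <- 1
    keys <- c(key_action0, 1L - key_action0)
    resp[keys == prev$key] <- 1
  }
  v <- params$beta_mb * qmb + params$beta_mf * qmf +
    params$pi * ch + params$rho * resp
  list(v = unname(v), ch = ch, resp = resp, net = unname(v[1] - v[2]))
}

#' Wiener first-passage log-density
#'
#' Log density of a Wiener diffusion (noise sigma = 1, unbiased start
#' `z = boundary / 2`) absorbing at the given boundary at time
#' `rt_s - ndt`.  Computed with the standard small-time / large-time series
#' switching scheme at truncation tolerance `tol`; observations with
#' `rt_s <= ndt` receive the floored log-density `log(1e-300)`.
#'
#' @param choice_upper Logical (vector): absorbed at the upper boundary?
#' @param rt_s Response time(s) in seconds.
#' @param net_drift Net drift rate(s).
#' @param boundary Boundary separation(s).
#' @param ndt Non-decision time(s) in seconds.
#' @param tol Series truncation tolerance.
#' @return Numeric vector of log densities.
#' @export
wiener_logpdf <- function(choice_upper, rt_s, net_drift, boundary, ndt,
                          tol = 1e-7) {
  stopifnot(all(boundary > 0), all(ndt >= 0))
  n <- max(length(choice_upper), length(rt_s), length(net_drift))
  wiener_lpdf_cpp(rep_len(as.numeric(rt_s), n),
                  rep_len(as.logical(choice_upper), n),
                  as.numeric(net_drift), as.numeric(boundary),
                  as.numeric(ndt), tol)
}

#' Probability of absorbing at the upper boundary (unbiased start)
#'
#' Closed form for `z = boundary / 2`, sigma = 1:
#' `P(upper) = 1 / (1 + exp(-net_drift * boundary))`.
#'
#' @param net_drift Net drift rate.
#' @param boundary Boundary separation.
#' @return Probability of an upper-boundary response.
#' @export
wiener_choice_prob <- function(net_drift, boundary) {
  stats::plogis(net_drift * boundary)
}

#' Sample first-stage choices and response times
#'
#' Euler-Maruyama simulation of the diffusion (`dx = v dt + dW`, start
#' `boundary / 2`); the returned RT is decision time plus non-decision
#' time.  Paths still unabsorbed at `rt_limit` are flagged as missed trials.
#'
#' @param net_drift Net drift rate.
#' @param params A [condition_params()] (uses `boundary` and `ndt`).
#' @param n Number of samples.
#' @param dt Simulation step in seconds.
#' @param rt_limit Response window in seconds.
#' @param seed Optional integer seed.
#' @return Data frame with `choice_upper`, `rt` (seconds) and `missed`.
#' @export
simulate_first_stage <- function(net_drift, params, n = 1, dt = 1e-3,
                                 rt_limit = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wiener_fpt_sim_cpp(as.integer(n), net_drift, params$boundary, params$ndt,
                     dt, rt_limit)
}

#' Convert a session data frame to the arrays used by the likelihood
#'
#' @param session Session data frame (see [simulate_agent_session()]).
#' @param dest Transition matrix.
#' @return List of integer/numeric vectors consumed by the compiled
#'   likelihood and a copy of `dest`.
#' @keywords internal
session_to_arrays <- function(session, dest = make_transition_structure()) {
  responded <- !is.na(session$a1)
  list(block = as.integer(session$block),
       cond = as.integer(session$condition == "other"),
       s1 = as.integer(session$s1),
       a1 = ifelse(responded, as.integer(session$a1), -1L),
       key = ifelse(responded, as.integer(session$key == "right"), -1L),
       s2 = ifelse(responded, as.integer(session$s2), -1L),
       valid = as.integer(!is.na(session$valid) & session$valid),
       learn = as.integer(responded & session$keypress),
       rt = ifelse(is.na(session$rt_ms), -1, session$rt_ms / 1000),
       reward = as.numeric(session$reward),
       dest = dest)
}

#' Session log-likelihood of the RLDDM
#'
#' Iterates trials in chronological order: computes the net drift from the
#' current learner state (condition-specific parameters selected per
#' trial's block), adds the Wiener log-density of the observed choice and
#' RT for valid trials, then applies the model-free update when a reward
#' was registered.  The learner state and the previous-choice indicators
#' reset at block boundaries; trials without a first-stage response clear
#' the previous-choice indicators and contribute nothing.
#'
#' @param params A 14-parameter vector ([param_names()]) or a matrix with
#'   one such vector per row.
#' @param session Session data frame.
#' @param dest Transition matrix.
#' @param tol Wiener series tolerance.
#' @param reset_per_block Reset learner state at block starts (default).
#' @param lambda_trace Eligibility trace (fixed at 1).
#' @return Numeric scalar (or vector, one per parameter row): summed
#'   log-likelihood over valid trials; 0 for an empty session.
#' @export
session_loglik <- function(params, session, dest = make_transition_structure(),
                           tol = 1e-7, reset_per_block = TRUE,
                           lambda_trace = 1) {
  if (is.null(dim(params))) params <- matrix(check_param_vector(params), 1)
  if (nrow(session) == 0) return(rep(0, nrow(params)))
  arr <- session_to_arrays(session, dest)
  session_loglik_cpp(params, arr, tol, reset_per_block, lambda_trace)
}
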