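test_that("model-free update follows the two prediction-error equations", {
  st <- learner_state()
  # alpha = 0.5, lambda = 1, all values at 4.5, reward 8:
  # d1 = 0, d2 = 3.5, both visited entries move to 6.25
  st2 <- mf_update(st, s1 = 0, a1 = 0, s2 = 1, reward = 8, alpha = 0.5)
  expect_equal(st2$delta1, 0)
  expect_equal(st2$delta2, 3.5)
  expect_equal(st2$q1[1, 1], 6.25)
  expect_equal(st2$q2[2], 6.25)
  # unchosen entries untouched
  expect_equal(st2$q1[1, 2], 4.5)
  expect_equal(st2$q1[2, ], c(a0 = 4.5, a1 = 4.5))
  expect_equal(st2$q2[1], 4.5)
  # zero learning rate changes nothing
  st3 <- mf_update(st, 0, 0, 1, 8, alpha = 0)
  expect_equal(st3$q1, st$q1)
  expect_equal(st3$q2, st$q2)
  # zero-error fixed point
  st4 <- mf_update(st, 1, 1, 0, 4.5, alpha = 0.7)
  expect_equal(st4$q1, st$q1)
  expect_equal(st4$q2, st$q2)
})

test_that("with lambda = 1 the chained stage-1 update equals alpha*(r - Q1)", {
  set.seed(21)
  for (i in 1:20) {
    st <- learner_state()
    st$q1 <- matrix(runif(4, 0, 9), 2, 2)
    st$q2 <- runif(2, 0, 9)
    a <- runif(1)
    r <- runif(1, 0, 9)
    s1 <- sample(0:1, 1); a1 <- sample(0:1, 1); s2 <- sample(0:1, 1)
    q1_old <- st$q1[s1 + 1, a1 + 1]
    st2 <- mf_update(st, s1, a1, s2, r, alpha = a, lambda_trace = 1)
    expect_equal(st2$q1[s1 + 1, a1 + 1], q1_old + a * (r - q1_old))
  }
})

test_that("model-based values read stage-2 values through the transitions", {
  st <- learner_state()
  st$q2 <- c(2, 7)
  dest <- make_transition_structure()
  q <- mb_values(st, dest)
  for (s in 1:2) for (a in 1:2) expect_equal(q[s, a], st$q2[dest[s, a] + 1])
  # an action leading to planet 1 is worth 7, to planet 0 worth 2
  expect_setequal(as.numeric(q[1, ]), c(2, 7))
  # equal stage-2 values make all four equal
  st$q2 <- c(5, 5)
  expect_true(all(mb_values(st, dest) == 5))
})

test_that("drift rate is the four-term sum with correct indicators", {
  st <- learner_state()
  st$q2 <- c(2, 7)            # planet values
  st$q1[1, ] <- c(6.25, 4.5)  # state 0 MF values
  dest <- make_transition_structure()
  p <- condition_params(beta_mb = 0.4, beta_mf = 0.2, pi = 0.1, rho = 0)
  # previous trial: same state, chose action 0
  prev <- list(state = 0, action = 0, key = 0)
  dr <- drift_rate(st, 0, p, dest, prev, key_action0 = 1L)
  # action 0 -> planet 0 (QMB 2)? depends on dest; compute expected directly
  qmb <- c(st$q2[dest[1, 1] + 1], st$q2[dest[1, 2] + 1])
  expect_equal(dr$ch, c(1, 0))
  v_exp <- 0.4 * qmb + 0.2 * c(6.25, 4.5) + 0.1 * c(1, 0)
  expect_equal(dr$v, unname(v_exp))
  expect_equal(dr$net, unname(v_exp[1] - v_exp[2]))
  # hand-worked numbers: QMB = (7, 2) when action 0 reaches planet 1
  st2 <- learner_state()
  st2$q2 <- c(2, 7)
  st2$q1[2, ] <- c(6.25, 4.5)
  dr2 <- drift_rate(st2, 1, p, dest, list(state = 1, action = 0, key = 0),
                    key_action0 = 1L)
  # state 1: action 0 -> planet 1 (value 7), action 1 -> planet 0 (value 2)
  expect_equal(dr2$v, c(0.4 * 7 + 0.2 * 6.25 + 0.1, 0.4 * 2 + 0.2 * 4.5))
  expect_equal(dr2$net, 4.15 - 1.70)
  # all weights zero -> zero net drift
  p0 <- condition_params()
  expect_equal(drift_rate(st, 0, p0, dest, prev, 0L)$net, 0)
  # symmetric values and indicators -> zero net drift
  st3 <- learner_state()
  expect_equal(drift_rate(st3, 0, p, dest, NULL, 0L)$net,
               0.4 * 4.5 + 0.2 * 4.5 - (0.4 * 4.5 + 0.2 * 4.5))
  # response stickiness follows key assignment, not action identity
  p_rho <- condition_params(rho = 0.3)
  dr3 <- drift_rate(learner_state(), 0, p_rho, dest,
                    list(state = 1, action = 1, key = 1), key_action0 = 1L)
  expect_equal(dr3$resp, c(1, 0))  # action 0 holds key "right" = prev key
  expect_equal(dr3$ch, c(0, 0))    # different state: no choice repetition
})

test_that("wiener density integrates to one and matches the closed-form
           choice probability", {
  for (par in list(c(v = 0, a = 1.5), c(v = 1, a = 2), c(v = -0.8, a = 1.1))) {
    fu <- function(t) exp(wiener_logpdf(TRUE, t, par["v"], par["a"], 0))
    fl <- function(t) exp(wiener_logpdf(FALSE, t, par["v"], par["a"], 0))
    pu <- integrate(fu, 0, 60, rel.tol = 1e-8)$value
    pl <- integrate(fl, 0, 60, rel.tol = 1e-8)$value
    expect_lt(abs(pu + pl - 1), 1e-3)
    expect_lt(abs(pu - wiener_choice_prob(par[["v"]], par[["a"]])), 1e-3)
  }
  # drift 0 with central start: each boundary takes half the mass
  expect_equal(wiener_choice_prob(0, 2), 0.5)
  # drift 1, boundary 2: P(upper) = 1/(1+exp(-2))
  expect_equal(wiener_choice_prob(1, 2), 1 / (1 + exp(-2)))
  # monotonicity in drift
  drifts <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(wiener_choice_prob(drifts, 1.5)) > 0))
})

test_that("rt at or below the non-decision time gets the floored density", {
  expect_equal(wiener_logpdf(TRUE, 0.2, 1, 1.5, 0.3), log(1e-300))
  expect_equal(wiener_logpdf(FALSE, 0.3, 1, 1.5, 0.3), log(1e-300))
  expect_gt(wiener_logpdf(TRUE, 0.5, 1, 1.5, 0.3), log(1e-300))
})

test_that("first-stage sampler matches symmetry and the mean-RT formula", {
  p <- condition_params(boundary = 2, ndt = 0.3)
  s0 <- simulate_first_stage(0, p, n = 4000, seed = 31, rt_limit = 60)
  expect_lt(abs(mean(s0$choice_upper) - 0.5), 0.03)
  s1 <- simulate_first_stage(1, p, n = 4000, seed = 32, rt_limit = 60)
  # mean decision time (a/2v) tanh(va/2) = 0.7616 s at v=1, a=2, plus ndt;
  # Euler discretisation at dt = 1e-3 biases upward by < ~2%
  expect_lt(abs(mean(s1$rt) - (0.7616 + 0.3)), 0.05)
  # simulated samples have finite density under the analytic likelihood
  lp <- wiener_logpdf(s1$choice_upper, s1$rt, 1, 2, 0.3)
  expect_true(all(is.finite(lp)))
  expect_true(all(lp > log(1e-300)))
})

test_that("session log-likelihood equals the brute-force oracle", {
  p <- default_test_params()
  ses <- tiny_session(p, seed = 7, n_per_block = 15, n_blocks = 4)
  expect_equal(session_loglik(p, ses), session_loglik_oracle(p, ses),
               tolerance = 1e-10)
  # with misses and fast trials present
  ses2 <- tiny_session(p, seed = 8, n_per_block = 15, n_blocks = 4,
                       keypress_p = 0.9, miss_rate = 0.1)
  expect_equal(session_loglik(p, ses2), session_loglik_oracle(p, ses2),
               tolerance = 1e-10)
  # other parameter values than the generating ones
  p2 <- p
  p2[["alpha_self"]] <- 0.2
  p2[["pi_other"]] <- -0.4
  p2[["ndt_self"]] <- 0.1
  expect_equal(session_loglik(p2, ses2), session_loglik_oracle(p2, ses2),
               tolerance = 1e-10)
})

test_that("session log-likelihood degenerate cases", {
  p <- default_test_params()
  ses <- tiny_session(p, seed = 9, n_per_block = 6)
  # empty session
  expect_equal(session_loglik(p, ses[0, ]), 0)
  # all trials invalid contribute nothing
  ses$valid <- FALSE
  ses$keypress <- FALSE
  expect_equal(session_loglik(p, ses), 0)
  # single valid trial equals its own wiener density
  ses3 <- tiny_session(p, seed = 10, n_per_block = 4)
  one <- ses3[1, , drop = FALSE]
  pc <- expand_condition_params(p)
  cp <- if (one$condition == "self") pc$self else pc$other
  st <- learner_state()
  dr <- drift_rate(st, one$s1, cp,
                   prev = NULL, key_action0 = 0L)
  expect_equal(session_loglik(p, one),
               wiener_logpdf(one$a1 == 0, one$rt_ms / 1000, dr$net,
                             cp$boundary, cp$ndt))
})

test_that("only visited entries change on an update (conservation)", {
  set.seed(41)
  st <- learner_state()
  for (i in 1:10) {
    s1 <- sample(0:1, 1); a1 <- sample(0:1, 1); s2 <- sample(0:1, 1)
    before_q1 <- st$q1; before_q2 <- st$q2
    st <- mf_update(st, s1, a1, s2, runif(1, 0, 9), alpha = 0.4)
    changed_q1 <- which(st$q1 != before_q1, arr.ind = TRUE)
    expect_true(nrow(changed_q1) <= 1)
    if (nrow(changed_q1) == 1)
      expect_equal(unname(changed_q1[1, ]), c(s1 + 1, a1 + 1))
    expect_true(sum(st$q2 != before_q2) <= 1)
  }
})
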