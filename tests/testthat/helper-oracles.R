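# Shared fixtures and independent oracles used across the test files.

# small scaffold with b blocks of n trials (alternating self/other blocks)
tiny_scaffold <- function(n_per_block = 10, n_blocks = 2, seed = 1) {
  set.seed(seed)
  n <- n_per_block * n_blocks
  conds <- rep(c("self", "other"), length.out = n_blocks)
  data.frame(trial = seq_len(n),
             block = rep(seq_len(n_blocks), each = n_per_block),
             condition = conds[rep(seq_len(n_blocks), each = n_per_block)],
             s1 = sample(0:1, n, replace = TRUE),
             action_left = sample(0:1, n, replace = TRUE),
             pay0 = runif(n, 0, 9), pay1 = runif(n, 0, 9),
             stringsAsFactors = FALSE)
}

default_test_params <- function() {
  participant_params(
    condition_params(beta_mb = 0.4, beta_mf = 0.3, alpha = 0.6, pi = 0.1,
                     rho = 0.05, boundary = 1.4, ndt = 0.28),
    diff_mb = -0.13, diff_mf = 0, other_alpha = 0.55, other_ndt = 0.24)
}

# Brute-force session log-likelihood: an explicit R loop over trials using
# the exported single-step operations, fully independent of the compiled
# likelihood path.
session_loglik_oracle <- function(params, session,
                                  dest = make_transition_structure()) {
  pc <- expand_condition_params(params)
  ll <- 0
  state <- learner_state()
  prev <- NULL
  cur_block <- -1L
  for (t in seq_len(nrow(session))) {
    tr <- session[t, ]
    if (tr$block != cur_block) {
      cur_block <- tr$block
      state <- learner_state()
      prev <- NULL
    }
    if (is.na(tr$a1)) {
      prev <- NULL
      next
    }
    cp <- if (tr$condition == "self") pc$self else pc$other
    key_num <- as.integer(tr$key == "right")
    key_a0 <- if (tr$a1 == 0) key_num else 1L - key_num
    dr <- drift_rate(state, tr$s1, cp, dest, prev, key_a0)
    if (isTRUE(tr$valid)) {
      ll <- ll + wiener_logpdf(tr$a1 == 0, tr$rt_ms / 1000, dr$net,
                               cp$boundary, cp$ndt)
    }
    if (isTRUE(tr$keypress)) {
      state <- mf_update(state, tr$s1, tr$a1, tr$s2, tr$reward, cp$alpha, 1)
    }
    prev <- list(state = tr$s1, action = tr$a1, key = key_num)
  }
  ll
}

# simulate a small session from a 14-parameter vector
tiny_session <- function(params = default_test_params(), seed = 3,
                         n_per_block = 10, n_blocks = 2,
                         keypress_p = 1, miss_rate = 0) {
  sc <- tiny_scaffold(n_per_block, n_blocks, seed)
  simulate_agent_session(list(params = params, keypress_p = keypress_p,
                              miss_rate = miss_rate), sc, seed = seed + 1)
}
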