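#' Task configuration for the two-step task
#'
#' Bundles the structural constants of the task: 4 blocks of 60 trials
#' (240 trials total, 2 self-related and 2 other-related blocks), a 1500 ms
#' first-stage response window, a 200 ms fast-response cutoff below which
#' trials count as invalid, drifting rewards on `[0, 9]` with Gaussian
#' random-walk steps of SD 2, a 20:1 points-to-currency conversion and an
#' 800 ms recipient cue.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param rt_limit_ms First-stage response window in milliseconds.
#' @param fast_rt_cutoff_ms Responses faster than this are invalid.
#' @param conversion_ratio Reward points per currency unit.
#' @param cue_duration_ms Duration of the recipient cue.
#' @param walk_sd Standard deviation of the reward random-walk increments.
#' @param reward_bounds Reflecting boundaries of the reward walks.
#' @param round_payoffs Round walk values to integers (off by default; the
#'   walks are kept continuous within the bounds).
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_blocks = 4L, trials_per_block = 60L,
                        rt_limit_ms = 1500, fast_rt_cutoff_ms = 200,
                        conversion_ratio = 20, cue_duration_ms = 800,
                        walk_sd = 2, reward_bounds = c(0, 9),
                        round_payoffs = FALSE) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, rt_limit_ms > 0,
            fast_rt_cutoff_ms >= 0, walk_sd >= 0,
            length(reward_bounds) == 2, reward_bounds[1] < reward_bounds[2])
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 n_trials = as.integer(n_blocks * trials_per_block),
                 rt_limit_ms = rt_limit_ms,
                 fast_rt_cutoff_ms = fast_rt_cutoff_ms,
                 conversion_ratio = conversion_ratio,
                 cue_duration_ms = cue_duration_ms,
                 walk_sd = walk_sd,
                 reward_bounds = reward_bounds,
                 round_payoffs = round_payoffs),
            class = "task_config")
}

#' Deterministic transition structure of the two-step task
#'
#' Each of the two first-stage states offers two spaceships (actions), and
#' each spaceship deterministically flies to one of the two planets
#' (second-stage states).  Within each state the two spaceships cover both
#' planets, so every planet is reachable from every first-stage state.
#'
#' @return A 2 x 2 integer matrix `dest` with `dest[s1 + 1, a1 + 1]` the
#'   0-based planet reached by action `a1` in state `s1`.
#' @export
make_transition_structure <- function() {
  # crossed mapping: state 0 (a0 -> planet 0, a1 -> planet 1),
  #                  state 1 (a0 -> planet 1, a1 -> planet 0)
  dest <- matrix(c(0L, 1L,
                   1L, 0L), nrow = 2, byrow = TRUE,
                 dimnames = list(state = c("s0", "s1"),
                                 action = c("a0", "a1")))
  dest
}

#' Transition indicator T(s2 | s1, a1)
#'
#' @param dest Transition matrix from [make_transition_structure()].
#' @param s2,s1,a1 0-based state/action indices.
#' @return 1 if choosing `a1` in `s1` leads to `s2`, else 0.
#' @export
transition_prob <- function(dest, s2, s1, a1) {
  as.numeric(dest[s1 + 1, a1 + 1] == s2)
}

#' Reflect values into an interval
#'
#' Applies the standard reflecting-boundary rule `x -> 2*hi - x` (or
#' `2*lo - x`) repeatedly until the value lies inside `[lo, hi]`; implemented
#' in closed form by folding over the period `2*(hi - lo)`.
#'
#' @param x Numeric vector.
#' @param lo,hi Interval bounds.
#' @return Reflected values, all inside `[lo, hi]`.
#' @export
reflect_bounds <- function(x, lo = 0, hi = 9) {
  stopifnot(hi > lo)
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + ifelse(y > r, 2 * r - y, y)
}

#' Simulate the two reward random walks
#'
#' Each planet's payoff drifts by independent Gaussian increments
#' (`Normal(0, walk_sd)`, default SD 2), reflecting at the boundaries 0 and
#' 9.  One planet is initialised uniformly in the low range `[0, 4]`, the
#' other in the high range `[5, 9]`; which planet starts high is random.
#'
#' @param config A [task_config()].
#' @param n_trials Length of the trajectories.
#' @param seed Optional integer seed.
#' @return A list of class `reward_walk` with `pay` (n_trials x 2 matrix),
#'   `walk_sd` and `bounds`.
#' @export
simulate_reward_walks <- function(config = task_config(),
                                  n_trials = config$n_trials, seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1)
    stop("n_trials must be a positive integer")
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)
  lo <- config$reward_bounds[1]
  hi <- config$reward_bounds[2]
  high_first <- sample(c(TRUE, FALSE), 1)
  init_low <- stats::runif(1, lo, 4)
  init_high <- stats::runif(1, 5, hi)
  init <- if (high_first) c(init_high, init_low) else c(init_low, init_high)
  # per-step increment, reflected into the bounds immediately
  pay <- matrix(NA_real_, n_trials, 2)
  for (j in 1:2) {
    x <- reflect_bounds(init[j], lo, hi)
    pay[1, j] <- x
    if (n_trials > 1) {
      incs <- stats::rnorm(n_trials - 1, 0, config$walk_sd)
      for (t in 2:n_trials) {
        x <- reflect_bounds(x + incs[t - 1], lo, hi)
        pay[t, j] <- x
      }
    }
  }
  if (isTRUE(config$round_payoffs)) pay <- round(pay)
  structure(list(pay = pay, walk_sd = config$walk_sd, bounds = c(lo, hi)),
            class = "reward_walk")
}

#' Generate the pair of pre-determined counterbalanced trial sequences
#'
#' Builds two full session scaffolds sharing the same first-stage state
#' order, the same left/right position assignment and the same two payoff
#' trajectories, and differing only in which blocks are self-related versus
#' other-related (the block-to-condition assignment of the second scaffold
#' is the self/other swap of the first).
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed.
#' @return A list of class `trial_sequence_pair` with elements `scaffold_a`
#'   and `scaffold_b` (data frames with columns `trial`, `block`,
#'   `condition`, `s1`, `action_left`, `pay0`, `pay1`) plus the shared
#'   `walk`.
#' @export
generate_trial_sequence_pair <- function(config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  walk <- simulate_reward_walks(config, n)
  s1 <- sample(0:1, n, replace = TRUE)
  action_left <- sample(0:1, n, replace = TRUE)
  block <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
  cond_a <- sample(rep(c("self", "other"), length.out = config$n_blocks))
  cond_b <- ifelse(cond_a == "self", "other", "self")
  scaffold <- function(cond) {
    data.frame(trial = seq_len(n), block = block,
               condition = cond[block], s1 = s1,
               action_left = action_left,
               pay0 = walk$pay[, 1], pay1 = walk$pay[, 2],
               stringsAsFactors = FALSE)
  }
  structure(list(scaffold_a = scaffold(cond_a), scaffold_b = scaffold(cond_b),
                 walk = walk, config = config),
            class = "trial_sequence_pair")
}
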