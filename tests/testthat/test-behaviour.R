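make_session_rows <- function(block, condition, s1, a1, s2, reward, valid,
                              trial = seq_along(block)) {
  data.frame(trial = trial, block = block, condition = condition, s1 = s1,
             a1 = a1, key = "left", rt_ms = 600, s2 = s2,
             keypress = TRUE, reward = reward, valid = valid,
             stringsAsFactors = FALSE)
}

test_that("stay table follows the trial-pair definition", {
  # prev: state 0 -> planet 1 (reward 8); current: state 1, reaches planet 1
  ses <- make_session_rows(block = c(1, 1), condition = "self",
                           s1 = c(0, 1), a1 = c(1, 0), s2 = c(1, 1),
                           reward = c(8, 3), valid = TRUE)
  tab <- build_stay_table(ses, id = 7)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$stay, 1L)
  expect_equal(tab$first_stage_same, 0L)
  expect_equal(tab$prev_outcome, 8)
  expect_equal(tab$self_other, 0.5)
  expect_equal(tab$id, 7)
  # different second-stage state -> stay = 0; same first stage -> 1
  ses2 <- make_session_rows(block = c(1, 1), condition = "other",
                            s1 = c(0, 0), a1 = c(1, 0), s2 = c(1, 0),
                            reward = c(5, 2), valid = TRUE)
  tab2 <- build_stay_table(ses2)
  expect_equal(tab2$stay, 0L)
  expect_equal(tab2$first_stage_same, 1L)
  expect_equal(tab2$self_other, -0.5)
})

test_that("stay table drops first trials, broken pairs and block crossings", {
  # single valid trial: no row
  one <- make_session_rows(1, "self", 0, 0, 0, 5, TRUE)
  expect_equal(nrow(build_stay_table(one)), 0)
  # invalid predecessor breaks the pair but the chain restarts after it
  ses <- make_session_rows(block = rep(1, 4), condition = "self",
                           s1 = c(0, 0, 0, 0), a1 = c(0, 0, 0, 0),
                           s2 = c(0, 0, 0, 0), reward = 5,
                           valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(build_stay_table(ses)), 1)
  # no stay rows across block boundaries
  ses2 <- make_session_rows(block = c(1, 2), condition = c("self", "other"),
                            s1 = c(0, 0), a1 = c(0, 0), s2 = c(0, 0),
                            reward = 5, valid = TRUE)
  expect_equal(nrow(build_stay_table(ses2)), 0)
  # row count identity on a simulated session: per block, valid runs of
  # consecutive trials each contribute (run length - 1) rows
  p <- default_test_params()
  ses3 <- tiny_session(p, seed = 17, n_per_block = 30, n_blocks = 4,
                       keypress_p = 0.95, miss_rate = 0.05)
  tab3 <- build_stay_table(ses3)
  expected <- 0
  for (b in unique(ses3$block)) {
    sb <- ses3[ses3$block == b, ]
    okt <- sb$trial[!is.na(sb$a1) & sb$valid]
    if (length(okt) >= 2) expected <- expected + sum(diff(okt) == 1)
  }
  expect_equal(nrow(tab3), expected)
})

test_that("stay regression recovers planted signatures (fast method)", {
  pair <- generate_trial_sequence_pair(seed = 18)
  # purely model-based cohort: strong previous-outcome main effect and a
  # null previous-outcome x first-stage interaction
  mb_agents <- lapply(1:25, function(i)
    list(id = i,
         params = participant_params(
           condition_params(beta_mb = 0.8, beta_mf = 0, alpha = 0.7,
                            boundary = 1.4, ndt = 0.25)),
         keypress_p = 1, miss_rate = 0))
  sessions <- simulate_cohort_sessions(mb_agents, pair, seed = 19)
  tab <- do.call(rbind, lapply(seq_along(sessions), function(i)
    build_stay_table(sessions[[i]], id = i)))
  fit <- fit_stay_regression(tab, "base", sampler_config("laplace"))
  s <- fit$summary
  expect_gt(s$mean[s$term == "po"], 0)
  expect_true(s$significant[s$term == "po"])
  expect_false(s$significant[s$term == "po:fs"])
  # uniform-random cohort: all slope HDIs contain zero
  rnd_agents <- lapply(1:25, function(i)
    list(id = i, params = participant_params(
      condition_params(boundary = 1.2, ndt = 0.25)),
      keypress_p = 1, miss_rate = 0))
  sessions0 <- simulate_cohort_sessions(rnd_agents, pair, seed = 20)
  tab0 <- do.call(rbind, lapply(seq_along(sessions0), function(i)
    build_stay_table(sessions0[[i]], id = i)))
  fit0 <- fit_stay_regression(tab0, "base", sampler_config("laplace"))
  slopes <- fit0$summary[fit0$summary$term != "(Intercept)", ]
  expect_true(all(!slopes$significant))
  # participant-level coefficients exist for every participant
  expect_equal(nrow(fit$participant_coefficients), 25)
})

test_that("effect-coding flip changes only the self-other signs", {
  p <- default_test_params()
  sessions <- lapply(1:8, function(i) tiny_session(p, seed = 20 + i,
                                                   n_per_block = 25,
                                                   n_blocks = 4))
  tab <- do.call(rbind, lapply(seq_along(sessions), function(i)
    build_stay_table(sessions[[i]], id = i)))
  fit1 <- fit_stay_regression(tab, "base", sampler_config("laplace"))
  tab_flip <- tab
  tab_flip$self_other <- -tab_flip$self_other
  fit2 <- fit_stay_regression(tab_flip, "base", sampler_config("laplace"))
  s1 <- fit1$summary; s2 <- fit2$summary
  so_terms <- grepl("so", s1$term)
  expect_equal(s2$mean[so_terms], -s1$mean[so_terms], tolerance = 1e-4)
  expect_equal(s2$mean[!so_terms], s1$mean[!so_terms], tolerance = 1e-4)
})

test_that("mcmc and laplace posterior means agree in sign on planted data", {
  skip_if_not_installed("rjags")
  pair <- generate_trial_sequence_pair(seed = 25)
  agents <- lapply(1:10, function(i)
    list(id = i, params = participant_params(
      condition_params(beta_mb = 0.7, beta_mf = 0.2, alpha = 0.7,
                       boundary = 1.4, ndt = 0.25)),
      keypress_p = 1, miss_rate = 0))
  sessions <- simulate_cohort_sessions(agents, pair, seed = 26)
  tab <- do.call(rbind, lapply(seq_along(sessions), function(i)
    build_stay_table(sessions[[i]], id = i)))
  lap <- fit_stay_regression(tab, "base", sampler_config("laplace"))
  mc <- fit_stay_regression(tab, "base",
                            sampler_config("mcmc", chains = 2,
                                           iterations = 600, warmup = 200,
                                           seed = 5))
  # the main learning signature is large; methods must agree on it
  po_l <- lap$summary$mean[lap$summary$term == "po"]
  po_m <- mc$summary$mean[mc$summary$term == "po"]
  expect_gt(po_l, 0)
  expect_gt(po_m, 0)
  expect_lt(abs(po_l - po_m), 0.5 * max(po_l, po_m) + 0.1)
  expect_true(all(c("summary", "participant_coefficients") %in% names(mc)))
})

test_that("visual stay summary splits by binarised outcome and state", {
  tab <- data.frame(id = 1, stay = c(1, 1, 0, 0, 1, 0),
                    prev_outcome = c(8, 7, 2, 1, 9, 3),
                    first_stage_same = c(1, 0, 1, 0, 1, 1),
                    self_other = c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5),
                    svo = NA)
  vs <- stay_visual_summary(tab)
  expect_equal(nrow(vs), 4)
  high_same <- vs$stay_prob[vs$prev_high & vs$first_stage_same == 1]
  expect_equal(high_same, 1)           # trials 1 and 5 both stayed
  expect_equal(sum(vs$n), 6)
  vs2 <- stay_visual_summary(tab, by_condition = TRUE)
  expect_true("condition" %in% names(vs2))
  expect_equal(sum(vs2$n), 6)
})

test_that("paired t-test matches the naive formula and handles edge cases", {
  set.seed(30)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  res <- paired_t(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(40)))
  expect_equal(res$dof, 39)
  expect_equal(res$d, mean(d) / sd(d))
  # identical vectors: zero effect, not an error
  res0 <- paired_t(x, x)
  expect_equal(res0$t, 0)
  expect_equal(res0$d, 0)
  expect_equal(res0$p, 1)
  # constant nonzero difference is degenerate
  expect_error(paired_t(x + 1, x))
  # planted d = 0.75 at n = 92 rejects essentially always
  rej <- replicate(200, {
    diffs <- rnorm(92, 0.75, 1)
    paired_t(diffs, rep(0, 92))$p < 0.05
  })
  expect_gte(mean(rej), 0.99)
})

test_that("paired t-test power follows the noncentral t", {
  # null case: power equals alpha
  expect_equal(power_paired_t(0, 92), 0.05, tolerance = 1e-10)
  # monotone in n
  ns <- c(10, 20, 40, 80, 160)
  pw <- sapply(ns, function(n) power_paired_t(0.3, n))
  expect_true(all(diff(pw) > 0))
  # Monte-Carlo cross-check at d = 0.5, n = 30
  set.seed(31)
  emp <- mean(replicate(4000, {
    d <- rnorm(30, 0.5, 1)
    t.test(d, alternative = "greater")$p.value < 0.05
  }))
  expect_lt(abs(emp - power_paired_t(0.5, 30)), 0.03)
})
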