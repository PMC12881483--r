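test_that("recovery-mode cohort respects the uniform ranges", {
  cfg <- cohort_config("recovery", n_agents = 100, seed = 2)
  cohort <- sample_cohort(cfg)
  pm <- do.call(rbind, lapply(cohort, `[[`, "params"))
  expect_equal(nrow(pm), 100)
  expect_true(all(pm[, "beta_mb_self"] >= -0.5 & pm[, "beta_mb_self"] <= 1))
  expect_true(all(pm[, "beta_mf_self"] >= -0.5 & pm[, "beta_mf_self"] <= 1))
  expect_true(all(pm[, "diff_mb"] >= -1 & pm[, "diff_mb"] <= 0.5))
  expect_true(all(pm[, "alpha_self"] >= 0 & pm[, "alpha_self"] <= 1))
  expect_true(all(abs(pm[, "pi_self"]) <= 1.2))
  expect_true(all(pm[, "bound_self"] >= 0.9 & pm[, "bound_self"] <= 2))
  expect_true(all(pm[, "ndt_self"] >= 0.02 & pm[, "ndt_self"] <= 0.55))
  # empty cohort
  expect_length(sample_cohort(cohort_config("recovery", n_agents = 0)), 0)
})

test_that("planted cohort carries the planted effects", {
  cfg <- cohort_config("planted", n_agents = 500, seed = 3)
  cohort <- sample_cohort(cfg)
  pm <- do.call(rbind, lapply(cohort, `[[`, "params"))
  svo <- sapply(cohort, `[[`, "svo")
  expect_true(all(svo >= -16.26 & svo <= 61.39))
  # mean Other-Self gaps near their planted values
  expect_lt(abs(mean(pm[, "diff_mb"]) - cfg$planted_diff_mb), 0.03)
  expect_lt(abs(mean(pm[, "ndt_other"] - pm[, "ndt_self"]) -
                  cfg$planted_diff_ndt), 0.01)
  expect_lt(abs(mean(pm[, "alpha_other"] - pm[, "alpha_self"]) -
                  cfg$planted_diff_alpha), 0.03)
  # copula-planted SVO correlation with the Self-Other gap within +-0.1
  gap_self_minus_other <- -pm[, "diff_mb"]
  expect_lt(abs(cor(svo, gap_self_minus_other) - cfg$svo_gap_cor), 0.1)
  # infeasible correlation errors
  expect_error(cohort_config("planted", svo_gap_cor = 1.2))
})

test_that("with planted effects off the mean gaps vanish", {
  cfg <- cohort_config("planted", n_agents = 600, planted_diff_mb = 0,
                       planted_diff_ndt = 0, planted_diff_alpha = 0,
                       svo_gap_cor = 0, seed = 4)
  pm <- do.call(rbind, lapply(sample_cohort(cfg), `[[`, "params"))
  expect_lt(abs(mean(pm[, "diff_mb"])), 0.03)
  expect_lt(abs(mean(pm[, "ndt_other"] - pm[, "ndt_self"])), 0.01)
  expect_lt(abs(mean(pm[, "alpha_other"] - pm[, "alpha_self"])), 0.03)
})

test_that("simulated sessions have the right structure and behaviour", {
  pair <- generate_trial_sequence_pair(seed = 6)
  # symmetric agent: near 50/50 choices
  p0 <- participant_params(condition_params(boundary = 1.5, ndt = 0.25))
  s0 <- simulate_agent_session(list(params = p0, keypress_p = 1,
                                    miss_rate = 0), pair$scaffold_a, seed = 7)
  expect_equal(nrow(s0), 240)
  expect_lt(abs(mean(s0$a1, na.rm = TRUE) - 0.5), 0.12)
  # valid flags consistent with the rt window
  resp <- !is.na(s0$a1)
  expect_true(all(s0$rt_ms[resp] <= 1500))
  expect_equal(s0$valid[resp], s0$rt_ms[resp] >= 200)
  expect_true(all(s0$reward[!resp] == 0))
  # strongly model-based agent on near-constant walks ends mostly on the
  # higher-paying planet
  sc <- pair$scaffold_a
  sc$pay0 <- 8; sc$pay1 <- 1
  pmb <- participant_params(condition_params(beta_mb = 3, alpha = 0.7,
                                             boundary = 1.5, ndt = 0.25))
  smb <- simulate_agent_session(list(params = pmb, keypress_p = 1,
                                     miss_rate = 0), sc, seed = 8)
  on_high <- mean(smb$s2 == 0, na.rm = TRUE)
  expect_gt(on_high, 0.8)
  # session io round-trips
  tmp <- tempfile(fileext = ".csv")
  write_session(s0, tmp)
  expect_equal(read_session(tmp), s0, tolerance = 1e-12)
  unlink(tmp)
})

test_that("random-agent null matches the fair-coin degenerate case", {
  pair <- generate_trial_sequence_pair(seed = 9)
  null_fc <- random_agent_null(pair$scaffold_a, n_agents = 50,
                               reference = "fair_coin", seed = 10)
  expect_equal(unname(null_fc$thresholds), rep(60 * log(2), 4))
  expect_true(all(null_fc$nll == 60 * log(2)))
  # percentile 100 equals the distribution maximum
  null_sm <- random_agent_null(pair$scaffold_a, n_agents = 200, seed = 11)
  null_max <- random_agent_null(pair$scaffold_a, n_agents = 200,
                                percentile = 100, seed = 11)
  expect_equal(unname(null_max$thresholds), apply(null_sm$nll, 2, max))
  # fitted reference overfits mildly: thresholds just below 60*ln2
  expect_true(all(null_sm$thresholds < 60 * log(2)))
  expect_true(all(null_sm$thresholds > 35))
})

test_that("exclusion rules remove invalid and random agents", {
  pair <- generate_trial_sequence_pair(seed = 12)
  null <- random_agent_null(pair$scaffold_a, n_agents = 400, seed = 13)
  # compliant structured agent
  p <- default_test_params()
  good <- lapply(1:3, function(i)
    simulate_agent_session(list(params = p, keypress_p = 1, miss_rate = 0),
                           pair$scaffold_a, seed = 20 + i))
  # uniform-random agents: drift weights all zero, fast boundary
  prand <- participant_params(condition_params(boundary = 0.8, ndt = 0.3))
  rand <- lapply(1:10, function(i)
    simulate_agent_session(list(params = prand, keypress_p = 1,
                                miss_rate = 0), pair$scaffold_a,
                           seed = 40 + i))
  # an agent with > 20% invalid trials
  lazy <- simulate_agent_session(list(params = p, keypress_p = 1,
                                      miss_rate = 0.35), pair$scaffold_a,
                                 seed = 60)
  sessions <- c(good, rand, list(lazy))
  res <- apply_exclusions(sessions, null)
  expect_true(all(res$keep[1:3]))
  expect_false(res$keep[14])
  expect_true(res$report$invalid_flag[14])
  expect_gte(res$report$invalid_fraction[14], 0.2)
  # majority of the planted random agents are flagged by the null rule
  expect_gte(sum(res$report$random_flag[4:13]), 6)
  expect_equal(res$n_excluded_invalid + res$n_excluded_random,
               sum(!res$keep))
})
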