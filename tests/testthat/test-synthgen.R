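test_that("bar response follows the DoG mass model", {
  cfg <- sim_config(amp_exc = 100, sigma_exc = 2, amp_inh = 40, sigma_inh = 8,
                    rundown_per_condition = 1)
  expect_identical(bar_response_mean(0, cfg, "baseline"), 0)
  # infinite-length limit: both erf terms -> 1
  expect_equal(bar_response_mean(1e6, cfg, "baseline"), 100 - 40)
  # quadrature oracle at a finite length
  expect_equal(bar_response_mean(40, cfg, "baseline"),
               oracle_bar_response(40, 100, 2, 40, 8), tolerance = 1e-9)
  for (L in c(0.5, 3, 11, 27)) {
    expect_equal(bar_response_mean(L, cfg, "baseline"),
                 oracle_bar_response(L, 100, 2, 40, 8), tolerance = 1e-9)
  }
  expect_error(bar_response_mean(-1, cfg), "non-negative")
})

test_that("condition switches act on the bar response as configured", {
  cfg <- sim_config(amp_exc = 100, sigma_exc = 2, amp_inh = 40, sigma_inh = 8,
                    surround_scale_drug = 0, rundown_per_condition = 0.9)
  # no surround under the drug: profile monotone nondecreasing in length
  prof <- bar_response_mean(c(0.5, 1, 2, 4, 8, 16, 32, 64), cfg, "drug")
  expect_true(all(diff(prof) >= 0))
  # run-down: recovery is rundown^2 x the baseline response
  L <- 12
  expect_equal(bar_response_mean(L, cfg, "recovery"),
               0.9^2 * bar_response_mean(L, cfg, "baseline"))
})

test_that("loom tuning is Gaussian with multiplicative competition", {
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18, rf_center_az = -10,
                    competition_gain_baseline = 0.6,
                    competition_gain_drug = 0.95,
                    rundown_per_condition = 1)
  expect_equal(loom_tuning_mean(-10, cfg), cfg$amp_exc)
  az <- seq(-30, 10, 5)
  alone <- loom_tuning_mean(az, cfg, competitor_present = FALSE)
  paired <- loom_tuning_mean(az, cfg, competitor_present = TRUE)
  expect_equal(paired, 0.6 * alone)
  paired_drug <- loom_tuning_mean(az, cfg, TRUE, "drug")
  alone_drug <- loom_tuning_mean(az, cfg, FALSE, "drug")
  expect_equal(paired_drug, 0.95 * alone_drug)
  # identity gain: competitor has no effect
  cfg1 <- update_sim_config(cfg, competition_gain_baseline = 1)
  expect_equal(loom_tuning_mean(az, cfg1, TRUE), loom_tuning_mean(az, cfg1, FALSE))
})

test_that("simulate_session honours the trial-count contract and determinism", {
  cfg <- sim_config(n_reps = 15, n_azimuths = 11)
  sess <- simulate_session(cfg, protocols = c("loom_single", "loom_pair"),
                           conditions = c("baseline", "drug", "recovery"),
                           seed = 5)
  expect_equal(nrow(sess), 15 * 11 * 2 * 3)
  expect_true(all(table(sess$condition) == 15 * 11 * 2))
  # trial interleaving: within a condition, protocols are mixed, not blocked
  first_block <- sess$protocol[sess$condition == "baseline"][1:40]
  expect_gt(dplyr::n_distinct(first_block), 1)
  # spike times sorted, inside the epoch
  expect_true(all(vapply(sess$spike_times_ms, function(s) !is.unsorted(s),
                         logical(1))))
  sess2 <- simulate_session(cfg, protocols = c("loom_single", "loom_pair"),
                            conditions = c("baseline", "drug", "recovery"),
                            seed = 5)
  expect_identical(sess, sess2)
  sess3 <- simulate_session(cfg, protocols = c("loom_single", "loom_pair"),
                            conditions = c("baseline", "drug", "recovery"),
                            seed = 6)
  expect_false(identical(sess$spike_times_ms, sess3$spike_times_ms))
  expect_error(simulate_session(cfg, protocols = character(0)), "protocol")
})

test_that("a silent site produces no spikes", {
  cfg <- sim_config(amp_exc = 1e-12, amp_inh = 0, spont_rate = 0, n_reps = 3)
  sess <- simulate_session(cfg, protocols = "bar", conditions = "baseline",
                           seed = 2)
  expect_true(all(lengths(sess$spike_times_ms) == 0))
})

test_that("simulated evoked rates converge to the configured mean", {
  # Poisson sampling oracle: with many repetitions the mean baseline-subtracted
  # rate in the count window approaches the expected evoked rate
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18, n_reps = 500,
                    n_azimuths = 3, rundown_per_condition = 1)
  sess <- simulate_session(cfg, protocols = "loom_single",
                           conditions = "baseline", seed = 42)
  rt <- build_rate_table(sess)
  at_peak <- rt$evoked_rate_spps[rt$stimulus_key == 0]
  expected <- loom_tuning_mean(0, cfg)
  se <- stats::sd(at_peak) / sqrt(length(at_peak))
  expect_lt(abs(mean(at_peak) - expected), 3 * se)
})

test_that("fast rate-path and spike-time path agree in distribution", {
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18, n_reps = 300,
                    n_azimuths = 3, rundown_per_condition = 1)
  rt_fast <- simulate_rate_table(cfg, protocols = "loom_single",
                                 conditions = "baseline", seed = 9)
  sess <- simulate_session(cfg, protocols = "loom_single",
                           conditions = "baseline", seed = 10)
  rt_full <- build_rate_table(sess)
  for (az in c(-5, 0, 5)) {
    a <- rt_fast$evoked_rate_spps[rt_fast$stimulus_key == az]
    b <- rt_full$evoked_rate_spps[rt_full$stimulus_key == az]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 4 * se)
  }
})

test_that("paired-site scenarios implement the drug switches", {
  cfg_a <- sim_config(site_id = "A", sigma_exc = 6, sigma_inh = 18,
                      competition_gain_baseline = 0.6, n_reps = 2)
  cfg_b <- update_sim_config(cfg_a, site_id = "B", rf_center_az = 34)
  # too-close RF centres rejected for distant-site scenarios
  expect_error(
    simulate_paired_sites(cfg_a, update_sim_config(cfg_b, rf_center_az = 20),
                          scenario = "imc_imc", seed = 1),
    "> 30 deg")
  ps <- simulate_paired_sites(cfg_a, cfg_b, scenario = "imc_imc", seed = 1)
  eff_a <- attr(ps, "config_a")
  # site-B inactivation: site A's paired-loom expectation equals S1 alone
  az <- azimuths <- seq(-25, 25, 5)
  expect_equal(loom_tuning_mean(az, eff_a, TRUE, "drug"),
               loom_tuning_mean(az, eff_a, FALSE, "drug"))

  sc <- simulate_paired_sites(cfg_a, cfg_b, scenario = "spread_control",
                              seed = 1)
  eff_a <- attr(sc, "config_a")
  # spread control: site A expected rates identical across conditions
  for (cond in c("drug", "recovery")) {
    expect_equal(loom_tuning_mean(az, eff_a, TRUE, cond),
                 loom_tuning_mean(az, eff_a, TRUE, "baseline"))
  }

  cfg_ot <- update_sim_config(cfg_a, surround_scale_drug = 0)
  po <- simulate_paired_sites(cfg_ot, update_sim_config(cfg_ot, site_id = "B"),
                              scenario = "ot10_imc", seed = 1)
  eff_b <- attr(po, "config_b")
  # inherited surround switch: Imc profile monotone when OT10 drug removes it
  prof <- bar_response_mean(c(1, 2, 4, 8, 16, 32), eff_b, "drug")
  expect_true(all(diff(prof) >= 0))
})

test_that("ground truth exposes recoverable parameters", {
  cfg <- sim_config(amp_exc = 100, sigma_exc = 2, amp_inh = 60, sigma_inh = 8,
                    competition_gain_baseline = 0.6,
                    competition_gain_drug = 0.95)
  gt <- ground_truth(cfg)
  expect_equal(gt$expected_slope, c(0.6, 0.95, 0.6))
  # SI invariant to run-down: identical across conditions here because the
  # drug leaves the surround untouched (surround_scale_drug = 1)
  expect_equal(gt$expected_si[1], gt$expected_si[3])
  expect_equal(gt$expected_si[1], gt$expected_si[2])
  # grid SI matches a direct oracle computation
  prof <- sapply(cfg$bar_lengths, oracle_bar_response, amp_exc = 100,
                 sigma_exc = 2, amp_inh = 60, sigma_inh = 8)
  expect_equal(gt$expected_si[1], oracle_si(prof, cfg$bar_lengths),
               tolerance = 1e-8)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sigma_exc = 8, sigma_inh = 2), "sigma")
  expect_error(sim_config(amp_exc = 10, amp_inh = 20), "amp")
  expect_error(sim_config(competition_gain_baseline = 1.5), "gain")
  expect_error(sim_config(rundown_per_condition = 0), "rundown")
  expect_error(sim_config(amp_exc = Inf), "finite")
})
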