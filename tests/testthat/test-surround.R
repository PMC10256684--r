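test_that("suppression index matches its definition", {
  # peak 100; three widest bars average 42
  si <- suppression_index(c(60, 100, 80, 40, 42, 44),
                          c(1, 4, 8, 16, 24, 40))
  expect_equal(si, (100 - 42) / 100)
  # monotone saturating profile: three widest equal the peak
  expect_equal(suppression_index(c(10, 50, 80, 80, 80, 80),
                                 c(1, 2, 4, 8, 16, 32)), 0)
  expect_error(suppression_index(c(1, 2, 3), c(1, 2, 3)), ">= 4")
  expect_warning(si0 <- suppression_index(c(-5, -1, -2, -3), c(1, 2, 4, 8)),
                 "undefined")
  expect_true(is.na(si0))
})

test_that("SI of the noise-free DoG profile matches the quadrature oracle", {
  cfg <- sim_config(amp_exc = 100, sigma_exc = 2, amp_inh = 60, sigma_inh = 8,
                    rundown_per_condition = 1)
  lengths <- c(0.5, 1, 2, 4, 8, 12, 16, 24, 32, 40)
  prof <- bar_response_mean(lengths, cfg, "baseline")
  oracle_prof <- sapply(lengths, oracle_bar_response, amp_exc = 100,
                        sigma_exc = 2, amp_inh = 60, sigma_inh = 8)
  expect_equal(suppression_index(prof, lengths),
               oracle_si(oracle_prof, lengths), tolerance = 1e-6)
})

test_that("SI is invariant to multiplicative run-down", {
  withr::local_seed(3)
  for (rep in 1:20) {
    means <- runif(8, 1, 100)
    lengths <- sort(runif(8, 0.5, 40))
    c_scale <- runif(1, 0.05, 20)
    expect_equal(suppression_index(c_scale * means, lengths),
                 suppression_index(means, lengths))
  }
  # and across simulator conditions when only run-down differs
  cfg <- sim_config(rundown_per_condition = 0.8, surround_scale_drug = 1)
  si_by_cond <- sapply(c("baseline", "drug", "recovery"), function(cond) {
    suppression_index(bar_response_mean(cfg$bar_lengths, cfg, cond),
                      cfg$bar_lengths)
  })
  expect_equal(unname(si_by_cond[2]), unname(si_by_cond[1]))
  expect_equal(unname(si_by_cond[3]), unname(si_by_cond[1]))
})

test_that("peak normalisation rescales but preserves shape and SI", {
  rt <- toy_rate_table(list(baseline = list(`1` = c(20, 30), `4` = c(90, 110),
                                            `8` = c(60, 70), `16` = c(38, 42),
                                            `32` = c(40, 44))))
  prof <- bar_length_profile(rt, "baseline")
  norm <- peak_normalize(prof)
  expect_equal(max(norm$mean_rate_spps), 1)
  expect_equal(attr(norm, "si"), attr(prof, "si"))
  # doubling all rates gives the identical normalised profile
  rt2 <- rt
  rt2$evoked_rate_spps <- 2 * rt2$evoked_rate_spps
  norm2 <- peak_normalize(bar_length_profile(rt2, "baseline"))
  expect_equal(norm2$mean_rate_spps, norm$mean_rate_spps)
})

test_that("competition slope is ordinary least squares over in-RF means", {
  d <- data.frame(rate_s1_alone = c(1, 2, 3, 4, 5),
                  rate_s1_with_s2 = c(1, 2, 3, 4, 5))
  expect_equal(competition_slope(d)$slope, 1)
  expect_equal(competition_slope(d)$intercept, 0)
  d$rate_s1_with_s2 <- 0.5 * d$rate_s1_alone
  expect_equal(competition_slope(d)$slope, 0.5)

  withr::local_seed(11)
  x <- runif(7, 0, 80)
  y <- 3 + 0.6 * x + rnorm(7, 0, 5)
  got <- competition_slope(data.frame(rate_s1_alone = x, rate_s1_with_s2 = y))
  want <- oracle_ols(x, y)
  expect_equal(got$slope, want[["slope"]], tolerance = 1e-10)
  expect_equal(got$intercept, want[["intercept"]], tolerance = 1e-10)

  # degenerate inputs are flagged, not errors
  expect_match(competition_slope(d[1:2, ])$flag, "fewer than 3")
  d0 <- data.frame(rate_s1_alone = rep(2, 5), rate_s1_with_s2 = 1:5)
  expect_match(competition_slope(d0)$flag, "zero variance")
})

test_that("slope is invariant to common multiplicative scaling of the pairs", {
  withr::local_seed(2)
  x <- runif(6, 10, 90)
  y <- 0.55 * x + rnorm(6, 0, 3)
  s1 <- competition_slope(data.frame(rate_s1_alone = x, rate_s1_with_s2 = y))
  s2 <- competition_slope(data.frame(rate_s1_alone = 0.7 * x,
                                     rate_s1_with_s2 = 0.7 * y))
  expect_equal(s2$slope, s1$slope, tolerance = 1e-12)
})

test_that("competition scatter pairs S1-alone with S1-and-S2 means per azimuth", {
  pairs <- list(baseline = list(
    `-5` = cbind(c(10, 12), c(6, 8)),
    `0` = cbind(c(50, 54), c(30, 34)),
    `5` = cbind(c(20, 24), c(12, 16))))
  rt <- toy_pair_rate_table(pairs)
  sc <- competition_scatter(rt, c(-5, 0, 5), "baseline")
  expect_equal(sc$rate_s1_alone, c(11, 52, 22))
  expect_equal(sc$rate_s1_with_s2, c(7, 32, 14))
  # azimuths outside the RF are ignored
  sc2 <- competition_scatter(rt, c(0, 5), "baseline")
  expect_equal(nrow(sc2), 2)
})

test_that("noise-free simulated pairs recover the configured gain exactly", {
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18,
                    competition_gain_baseline = 0.6, rundown_per_condition = 1)
  az <- seq(-10, 10, 5)
  alone <- loom_tuning_mean(az, cfg, FALSE)
  paired <- loom_tuning_mean(az, cfg, TRUE)
  got <- competition_slope(data.frame(rate_s1_alone = alone,
                                      rate_s1_with_s2 = paired))
  expect_equal(got$slope, 0.6, tolerance = 1e-10)
  expect_equal(got$intercept, 0, tolerance = 1e-10)
})
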