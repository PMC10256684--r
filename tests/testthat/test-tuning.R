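test_that("tuning curve means and SEMs match hand computation", {
  rt <- toy_rate_table(list(baseline = list(`-5` = c(1, 2, 3),
                                            `0` = c(10, 10, 10),
                                            `5` = c(2, 4, 6))),
                       protocol = "loom_single")
  tc <- build_tuning_curve(rt)
  expect_equal(tc$azimuth_deg, c(-5, 0, 5))
  expect_equal(tc$mean_rate_spps, c(2, 10, 4))
  expect_equal(tc$sem_spps, c(1 / sqrt(3), 0, 2 / sqrt(3)))
  expect_equal(tc$n_reps, rep(3L, 3))

  expect_error(build_tuning_curve(
    toy_rate_table(list(baseline = list(`0` = 1:5)), protocol = "loom_single")),
    ">= 3 azimuths")
  expect_warning(build_tuning_curve(
    toy_rate_table(list(baseline = list(`-5` = 1, `0` = 2, `5` = 3)),
                   protocol = "loom_single")),
    "< 2 repetitions")
})

test_that("gaussian fit recovers noise-free parameters", {
  x <- seq(-25, 25, 5)
  true <- c(amplitude = 80, center = -3, sigma = 7, offset = 5)
  curve <- tibble::tibble(
    azimuth_deg = x,
    mean_rate_spps = true["offset"] + true["amplitude"] *
      exp(-(x - true["center"])^2 / (2 * true["sigma"]^2)))
  fit <- fit_gaussian(curve)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 80, tolerance = 1e-6)
  expect_equal(fit$center_deg, -3, tolerance = 1e-6)
  expect_equal(fit$sigma_deg, 7, tolerance = 1e-6)
  expect_equal(fit$offset, 5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(tidy(fit)$estimate[1], fit$amplitude)
})

test_that("a flat curve is flagged degenerate, not an error", {
  curve <- tibble::tibble(azimuth_deg = seq(-20, 20, 5),
                          mean_rate_spps = rep(4, 9))
  fit <- fit_gaussian(curve)
  expect_true(fit$degenerate)
  expect_lt(abs(fit$amplitude), 1e-4)
})

test_that("gaussian fit rss is near the dense grid-search optimum", {
  withr::local_seed(7)
  x <- seq(-25, 25, 5)
  y <- 3 + 60 * exp(-(x - 4)^2 / (2 * 6^2)) + rnorm(length(x), 0, 4)
  fit <- fit_gaussian(tibble::tibble(azimuth_deg = x, mean_rate_spps = y))
  # oracle: grid over (center, sigma), closed-form LS for amplitude/offset
  grid_rss <- function(center, sigma) {
    g <- exp(-(x - center)^2 / (2 * sigma^2))
    sum(stats::lm(y ~ g)$residuals^2)
  }
  best <- min(outer(seq(-25, 25, 0.25), seq(2.5, 50, 0.25),
                    Vectorize(grid_rss)))
  expect_lt(fit$rss, best * 1.01)
})

test_that("gaussian fit scales with the data", {
  withr::local_seed(1)
  x <- seq(-25, 25, 5)
  y <- 2 + 50 * exp(-(x + 5)^2 / 72) + rnorm(length(x), 0, 2)
  f1 <- fit_gaussian(tibble::tibble(azimuth_deg = x, mean_rate_spps = y))
  f2 <- fit_gaussian(tibble::tibble(azimuth_deg = x, mean_rate_spps = 3 * y))
  expect_equal(f2$amplitude, 3 * f1$amplitude, tolerance = 1e-4)
  expect_equal(f2$offset, 3 * f1$offset, tolerance = 1e-4)
  expect_equal(f2$center_deg, f1$center_deg, tolerance = 1e-4)
  expect_equal(f2$sigma_deg, f1$sigma_deg, tolerance = 1e-4)
})

test_that("RF estimation keeps the contiguous significant run around the peak", {
  # strongly driven centre, silent flanks: only the centre is in-RF
  rt <- toy_rate_table(list(baseline = list(
    `-10` = rep(0, 8), `-5` = rep(0, 8),
    `0` = c(40, 52, 47, 55, 38, 49, 51, 44),
    `5` = rep(0, 8), `10` = rep(0, 8))), protocol = "loom_single")
  rf <- estimate_rf(rt)
  expect_equal(in_rf_azimuths(rf), 0)
  expect_equal(rf_center_az(rf), 0)

  # an isolated significant azimuth far from the peak is excluded
  rt2 <- toy_rate_table(list(baseline = list(
    `-10` = c(5, 6, 7, 5, 6, 7, 5, 6),
    `-5` = c(-1, 1, -2, 2, -1, 1, -2, 2),
    `0` = c(40, 52, 47, 55, 38, 49, 51, 44),
    `5` = c(20, 25, 22, 27, 24, 21, 26, 23),
    `10` = c(-1, 1, -2, 2, -1, 1, -2, 2))), protocol = "loom_single")
  rf2 <- estimate_rf(rt2)
  expect_equal(in_rf_azimuths(rf2), c(0, 5))

  # all-silent site: no RF
  rt3 <- toy_rate_table(list(baseline = list(
    `-5` = rep(0, 8), `0` = rep(0, 8), `5` = rep(0, 8))),
    protocol = "loom_single")
  expect_error(estimate_rf(rt3), "no RF detected")
})

test_that("simulated peak azimuth lands within one grid step of the RF centre", {
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18, rf_center_az = 10)
  hits <- sapply(1:25, function(i) {
    rt <- simulate_rate_table(cfg, protocols = "loom_single",
                              conditions = "baseline", seed = 100 + i)
    rf <- estimate_rf(rt)
    abs(rf_center_az(rf) - 10) <= cfg$azimuth_step
  })
  expect_gt(mean(hits), 0.8)
})

test_that("in-RF set grows with excitatory amplitude (majority over seeds)", {
  n_in_rf <- function(amp, seeds) {
    sapply(seeds, function(i) {
      cfg <- sim_config(sigma_exc = 6, sigma_inh = 18, amp_exc = amp,
                        amp_inh = 10)
      rt <- simulate_rate_table(cfg, protocols = "loom_single",
                                conditions = "baseline", seed = i)
      length(in_rf_azimuths(estimate_rf(rt)))
    })
  }
  seeds <- 1:20
  expect_gt(mean(n_in_rf(150, seeds) >= n_in_rf(30, seeds)), 0.7)
})
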