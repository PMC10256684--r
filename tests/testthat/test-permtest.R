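test_that("identical constant conditions give p = 1 and an all-zero null", {
  rates <- lapply(c(1, 2, 4, 8), function(L) rep(10, 4))
  names(rates) <- c(1, 2, 4, 8)
  rt <- toy_rate_table(list(baseline = rates, drug = rates))
  pt <- perm_test_si(rt, n_perm = 200, seed = 1)
  expect_equal(pt$observed, 0)
  expect_true(all(pt$null_values == 0))
  expect_equal(pt$p_value, 1)

  pairs <- list(`-5` = cbind(rep(8, 3), rep(5, 3)),
                `0` = cbind(rep(20, 3), rep(12, 3)),
                `5` = cbind(rep(12, 3), rep(7, 3)))
  prt <- toy_pair_rate_table(list(baseline = pairs, drug = pairs))
  pt2 <- perm_test_slope(prt, c(-5, 0, 5), n_perm = 200, seed = 1)
  expect_equal(pt2$p_value, 1)
})

test_that("exhaustive SI test equals independent enumeration on toy data", {
  withr::local_seed(42)
  for (rep in 1:5) {
    rates_a <- list(`2` = round(runif(2, 0, 50), 1),
                    `8` = round(runif(2, 0, 50), 1),
                    `16` = round(runif(2, 0, 50), 1),
                    `32` = round(runif(2, 0, 50), 1))
    rates_b <- lapply(rates_a, function(v) round(v * runif(1, 0.3, 1.2), 1))
    rt <- toy_rate_table(list(baseline = rates_a, drug = rates_b))
    got <- perm_test_si(rt, exhaustive = TRUE)
    want <- oracle_perm_si_exhaustive(rates_a, rates_b, sign = 1)
    expect_equal(got$p_value, want$p)
    expect_equal(got$observed, want$observed)
    expect_equal(sort(got$null_values), sort(want$null))
    expect_equal(length(got$null_values), choose(4, 2)^4)
  }
})

test_that("exhaustive slope test equals independent enumeration on toy data", {
  withr::local_seed(7)
  for (rep in 1:3) {
    mk <- function(mu, g) cbind(mu + runif(2, -2, 2), g * mu + runif(2, -2, 2))
    pairs_a <- list(`-5` = mk(20, 0.5), `0` = mk(60, 0.5), `5` = mk(30, 0.5))
    pairs_b <- list(`-5` = mk(20, 1), `0` = mk(60, 1), `5` = mk(30, 1))
    rt <- toy_pair_rate_table(list(baseline = pairs_a, drug = pairs_b))
    got <- perm_test_slope(rt, c(-5, 0, 5), exhaustive = TRUE)
    colnames(pairs_a$`-5`) <- NULL
    want <- oracle_perm_slope_exhaustive(pairs_a, pairs_b, sign = 1)
    expect_equal(got$p_value, want$p)
    expect_equal(got$observed, want$observed)
    expect_equal(sort(got$null_values), sort(want$null))
  }
})

test_that("monte carlo p approaches the exhaustive p", {
  withr::local_seed(3)
  rates_a <- list(`2` = runif(3, 20, 60), `8` = runif(3, 40, 90),
                  `16` = runif(3, 10, 50), `32` = runif(3, 5, 40))
  rates_b <- lapply(rates_a, function(v) v * 0.8 + runif(3, -5, 5))
  rt <- toy_rate_table(list(baseline = rates_a, drug = rates_b))
  exact <- perm_test_si(rt, exhaustive = TRUE)$p_value
  mc <- perm_test_si(rt, n_perm = 4000, seed = 99)$p_value
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc - exact), 4 * se + 1e-3)
})

test_that("exchanging condition labels flips the observed statistic", {
  withr::local_seed(5)
  rates_a <- lapply(stats::setNames(c(1, 4, 8, 16), c(1, 4, 8, 16)),
                    function(L) runif(5, 10, 80))
  rates_b <- lapply(rates_a, function(v) v * 0.6)
  rt <- toy_rate_table(list(baseline = rates_a, drug = rates_b))
  fwd <- perm_test_si(rt, "baseline", "drug", n_perm = 10, seed = 1)
  rev <- perm_test_si(rt, "drug", "baseline", n_perm = 10, seed = 1)
  expect_equal(fwd$observed, -rev$observed)
  # and the direction argument flips it too
  alt <- perm_test_si(rt, "baseline", "drug", n_perm = 10, seed = 1,
                      direction = "b_minus_a")
  expect_equal(alt$observed, -fwd$observed)
})

test_that("permutation draws are seed-reproducible", {
  cfg <- default_design_config("imc_gaba_barlength")
  rt <- simulate_rate_table(cfg, protocols = "bar",
                            conditions = c("baseline", "drug"), seed = 21)
  p1 <- perm_test_si(rt, n_perm = 300, seed = 8)
  p2 <- perm_test_si(rt, n_perm = 300, seed = 8)
  expect_identical(p1$null_values, p2$null_values)
  p3 <- perm_test_si(rt, n_perm = 300, seed = 9)
  expect_false(identical(p1$null_values, p3$null_values))
  # different seeds agree within Monte-Carlo error
  expect_lt(abs(p1$p_value - p3$p_value),
            4 * sqrt(0.25 / 300) + 1e-6)
})

test_that("input contract violations error", {
  rates_a <- list(`1` = 1:3, `2` = 1:3, `4` = 1:3, `8` = 1:3)
  rates_b <- list(`1` = 1:3, `2` = 1:3, `4` = 1:3, `16` = 1:3)
  rt <- toy_rate_table(list(baseline = rates_a, drug = rates_b))
  expect_error(perm_test_si(rt), "same bar-length grid")
  rt2 <- toy_rate_table(list(baseline = rates_a, drug = rates_a))
  expect_error(perm_test_si(rt2, n_perm = 0), "n_perm")
  pairs <- list(`-5` = cbind(1:3, 1:3), `0` = cbind(1:3, 1:3))
  prt <- toy_pair_rate_table(list(baseline = pairs, drug = pairs))
  expect_error(perm_test_slope(prt, c(-5, 0)), ">= 3 in-RF azimuths")
})

test_that("the slope test has power for a released competition gain", {
  # g: 0.6 (baseline) -> 1.0 (drug); detection rate over simulated sites
  cfg <- sim_config(sigma_exc = 6, sigma_inh = 18,
                    competition_gain_baseline = 0.6,
                    competition_gain_drug = 1.0)
  hits <- vapply(1:60, function(i) {
    rt <- simulate_rate_table(cfg, protocols = c("loom_single", "loom_pair"),
                              conditions = c("baseline", "drug"),
                              seed = 5000 + i)
    pt <- perm_test_slope(rt, seq(-10, 10, 5), n_perm = 500, seed = i)
    pt$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
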