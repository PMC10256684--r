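# Repetition-shuffling permutation tests for per-site condition comparisons.
#
# Null model: at each stimulus value independently, the pooled per-repetition
# rates (or rate-pairs) of the two conditions are randomly reassigned to two
# pseudo-conditions of the original sizes; the statistic (SI or slope) is
# recomputed from the pseudo-condition means and the difference stored. The
# p-value is the proportion of permutations whose difference is greater than
# or equal to the observed difference (literal proportion; the observed value
# is not added to the null set, so p = 0 is possible).

# relative tolerance used when comparing null values to the observed
# difference, guarding floating-point noise in exact ties
.perm_tol <- function(obs) 1e-9 * (1 + abs(obs))

new_perm_test <- function(statistic_name, observed, null_values, n_perm,
                          seed, direction, method) {
  p <- sum(null_values >= observed - .perm_tol(observed), na.rm = TRUE) /
    length(null_values)
  structure(list(statistic_name = statistic_name,
                 observed = observed,
                 null_values = null_values,
                 p_value = p,
                 n_perm = n_perm,
                 seed = seed,
                 direction = direction,
                 method = method),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s (%s, %s)\n", x$statistic_name, x$direction,
              x$method))
  cat(sprintf("  observed difference = %.6g; p = %.4g (%d permutations%s)\n",
              x$observed, x$p_value, length(x$null_values),
              if (x$method == "monte_carlo") paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_name, observed = x$observed,
                 p_value = x$p_value, n_perm = length(x$null_values),
                 direction = x$direction, method = x$method)
}

#' @method glance perm_test
#' @export
glance.perm_test <- tidy.perm_test

# split per-repetition values by stimulus for one condition; returns a list
# of numeric matrices (reps x n_value_cols), names = stimulus values
split_by_stimulus <- function(rate_table, condition, protocols, cols) {
  rows <- rate_table[rate_table$condition == condition &
                       rate_table$protocol %in% protocols, , drop = FALSE]
  keys <- sort(unique(rows$stimulus_key))
  lapply(stats::setNames(keys, keys), function(k) {
    sub <- rows[rows$stimulus_key == k, , drop = FALSE]
    as.matrix(sub[order(sub$repetition_index), cols, drop = FALSE])
  })
}

check_shared_grid <- function(a, b, what) {
  if (!identical(names(a), names(b))) {
    stop("conditions were not measured on the same ", what, " grid",
         call. = FALSE)
  }
  if (length(a) == 0) stop("no ", what, " values found", call. = FALSE)
}

# random assignments: for stimulus value with pooled size m and group size
# n_a, draw n_perm index sets; returns n_a x n_perm integer matrix
random_assignments <- function(m, n_a, n_perm) {
  vapply(seq_len(n_perm), function(k) sample.int(m, n_a),
         integer(n_a))
}

# exhaustive assignments: all choose(m, n_a) index sets as a matrix
exhaustive_assignments <- function(m, n_a) {
  utils::combn(m, n_a)
}

exhaustive_grid <- function(n_combos, limit = 250000) {
  total <- prod(n_combos)
  if (total > limit) {
    stop("exhaustive enumeration would need ", format(total, big.mark = ","),
         " assignments (limit ", limit, "); use Monte Carlo permutations",
         call. = FALSE)
  }
  as.matrix(expand.grid(lapply(n_combos, seq_len)))
}

# per-stimulus pseudo-condition mean matrices for one value column.
# pools: list per stimulus of pooled vectors; assign: list per stimulus of
# index matrices (n_a x K, same K everywhere).
pseudo_means <- function(pools, assigns, n_a, n_b) {
  K <- ncol(assigns[[1]])
  L <- length(pools)
  mA <- matrix(0, L, K)
  mB <- matrix(0, L, K)
  for (l in seq_len(L)) {
    v <- pools[[l]]
    sumsA <- colSums(matrix(v[assigns[[l]]], nrow = n_a[l]))
    mA[l, ] <- sumsA / n_a[l]
    mB[l, ] <- (sum(v) - sumsA) / n_b[l]
  }
  list(a = mA, b = mB)
}

# vectorised SI over columns of a means matrix whose rows are sorted by length
si_columns <- function(m) {
  peak <- apply(m, 2, max)
  asym <- colMeans(m[nrow(m) - 2:0, , drop = FALSE])
  ifelse(peak > 0, (peak - asym) / peak, NA_real_)
}

# vectorised OLS slope of y-means on x-means across rows, per column
slope_columns <- function(xm, ym) {
  L <- nrow(xm)
  sx <- colSums(xm); sy <- colSums(ym)
  sxx <- colSums(xm^2); sxy <- colSums(xm * ym)
  denom <- sxx - sx^2 / L
  unname(ifelse(denom > 0, (sxy - sx * sy / L) / denom, NA_real_))
}

#' Permutation test for a change in suppression index
#'
#' Repetition-shuffling test for a difference in SI between two conditions.
#' At each bar length independently, the pooled per-repetition rates of the
#' two conditions are reassigned at random to two pseudo-conditions of the
#' original sizes; the SI of each pseudo-condition's mean profile is computed
#' and the difference stored. The p-value is the proportion of permutations
#' with a difference greater than or equal to the observed one (one-sided).
#'
#' @param rate_table A rate table containing bar-protocol rows for both
#'   conditions at the same bar lengths.
#' @param cond_a,cond_b Condition labels to compare. The default orientation
#'   (`"a_minus_b"`) tests for SI larger in `cond_a` (e.g. baseline) than in
#'   `cond_b` (e.g. drug), the predicted direction when the manipulation
#'   weakens the classical surround.
#' @param n_perm Number of random permutations (default 500).
#' @param seed Integer seed for the permutation draws.
#' @param exhaustive If `TRUE`, enumerate every balanced reassignment instead
#'   of sampling (only feasible for small repetition counts; the p-value is
#'   then exact).
#' @param direction `"a_minus_b"` or `"b_minus_a"`; the sign convention of the
#'   one-sided statistic.
#' @return A `perm_test` object (observed difference, null values, p-value,
#'   seed, direction, method); see also [tidy()].
#' @export
perm_test_si <- function(rate_table, cond_a = "baseline", cond_b = "drug",
                         n_perm = 500, seed = 1L, exhaustive = FALSE,
                         direction = c("a_minus_b", "b_minus_a")) {
  direction <- match.arg(direction)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  a <- split_by_stimulus(rate_table, cond_a, "bar", "evoked_rate_spps")
  b <- split_by_stimulus(rate_table, cond_b, "bar", "evoked_rate_spps")
  check_shared_grid(a, b, "bar-length")
  lengths <- as.numeric(names(a))
  if (length(lengths) < 4) {
    stop("suppression index needs >= 4 distinct bar lengths", call. = FALSE)
  }
  n_a <- vapply(a, nrow, integer(1))
  n_b <- vapply(b, nrow, integer(1))
  pools <- purrr::map2(a, b, function(x, y) c(x[, 1], y[, 1]))

  sgn <- if (direction == "a_minus_b") 1 else -1
  obs <- sgn * (suppression_index(vapply(a, mean, numeric(1)), lengths) -
                  suppression_index(vapply(b, mean, numeric(1)), lengths))

  if (exhaustive) {
    combos <- purrr::map2(n_a + n_b, n_a, exhaustive_assignments)
    grid <- exhaustive_grid(unname(vapply(combos, ncol, numeric(1))))
    assigns <- purrr::map(seq_along(combos), function(l) {
      combos[[l]][, grid[, l], drop = FALSE]
    })
    method <- "exhaustive"
    n_used <- nrow(grid)
  } else {
    assigns <- withr::with_seed(as.integer(seed), {
      purrr::map2(n_a + n_b, n_a, random_assignments, n_perm = n_perm)
    })
    method <- "monte_carlo"
    n_used <- n_perm
  }
  pm <- pseudo_means(pools, assigns, n_a, n_b)
  null_values <- sgn * (si_columns(pm$a) - si_columns(pm$b))
  new_perm_test("si_difference", obs, null_values, n_used, seed, direction,
                method)
}

#' Permutation test for a change in competitive-suppression slope
#'
#' Repetition-shuffling test for a difference in competition slope between two
#' conditions. The unit of reassignment is the per-repetition rate *pair*
#' (S1-alone, S1-with-S2) at each in-RF azimuth; pairs are never split. For
#' each permutation the per-azimuth mean pairs of the two pseudo-conditions
#' are computed and an OLS slope (free intercept) fitted to each; the
#' difference of slopes is stored. The p-value is the proportion of null
#' differences greater than or equal to the observed one.
#'
#' @param rate_table A rate table with `loom_single` and `loom_pair` rows for
#'   both conditions (paired by `repetition_index` within azimuth).
#' @param in_rf_azimuths Azimuths (deg) inside the RF; the slope uses only
#'   these (at least 3 required).
#' @inheritParams perm_test_si
#' @param direction `"b_minus_a"` (default) or `"a_minus_b"`. With
#'   `cond_a = "baseline"` and `cond_b = "drug"`, `"b_minus_a"` tests for a
#'   slope increase under the drug — the predicted release from competitive
#'   suppression.
#' @return A `perm_test` object.
#' @export
perm_test_slope <- function(rate_table, in_rf_azimuths,
                            cond_a = "baseline", cond_b = "drug",
                            n_perm = 500, seed = 1L, exhaustive = FALSE,
                            direction = c("b_minus_a", "a_minus_b")) {
  direction <- match.arg(direction)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(in_rf_azimuths) < 3) {
    stop("slope permutation test needs >= 3 in-RF azimuths", call. = FALSE)
  }
  pairs_of <- function(cond) {
    alone <- split_by_stimulus(rate_table, cond, "loom_single",
                               "evoked_rate_spps")
    pair <- split_by_stimulus(rate_table, cond, "loom_pair",
                              "evoked_rate_spps")
    check_shared_grid(alone, pair, "azimuth")
    keep <- names(alone)[as.numeric(names(alone)) %in% in_rf_azimuths]
    purrr::map(stats::setNames(keep, keep), function(k) {
      if (nrow(alone[[k]]) != nrow(pair[[k]])) {
        stop("unequal repetition counts for S1-alone and S1-with-S2 at ",
             "azimuth ", k, call. = FALSE)
      }
      cbind(x = alone[[k]][, 1], y = pair[[k]][, 1])
    })
  }
  a <- pairs_of(cond_a)
  b <- pairs_of(cond_b)
  check_shared_grid(a, b, "azimuth")
  if (length(a) < 3) {
    stop("fewer than 3 in-RF azimuths with measured rate-pairs", call. = FALSE)
  }
  n_a <- vapply(a, nrow, integer(1))
  n_b <- vapply(b, nrow, integer(1))
  pools_x <- purrr::map2(a, b, function(p, q) c(p[, "x"], q[, "x"]))
  pools_y <- purrr::map2(a, b, function(p, q) c(p[, "y"], q[, "y"]))

  slope_of <- function(mats) {
    xm <- vapply(mats, function(m) mean(m[, "x"]), numeric(1))
    ym <- vapply(mats, function(m) mean(m[, "y"]), numeric(1))
    slope_columns(cbind(xm), cbind(ym))
  }
  sgn <- if (direction == "b_minus_a") 1 else -1
  obs <- sgn * (slope_of(b) - slope_of(a))

  if (exhaustive) {
    combos <- purrr::map2(n_a + n_b, n_a, exhaustive_assignments)
    grid <- exhaustive_grid(unname(vapply(combos, ncol, numeric(1))))
    assigns <- purrr::map(seq_along(combos), function(l) {
      combos[[l]][, grid[, l], drop = FALSE]
    })
    method <- "exhaustive"
    n_used <- nrow(grid)
  } else {
    assigns <- withr::with_seed(as.integer(seed), {
      purrr::map2(n_a + n_b, n_a, random_assignments, n_perm = n_perm)
    })
    method <- "monte_carlo"
    n_used <- n_perm
  }
  # pairs travel as units: the same index set selects x and y
  pmx <- pseudo_means(pools_x, assigns, n_a, n_b)
  pmy <- pseudo_means(pools_y, assigns, n_a, n_b)
  null_values <- sgn * (slope_columns(pmx$b, pmy$b) -
                          slope_columns(pmx$a, pmy$a))
  new_perm_test("slope_difference", obs, null_values, n_used, seed, direction,
                method)
}
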