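#' Assemble a spatial tuning curve
#'
#' Per-azimuth mean and standard error of the per-repetition evoked rates for
#' one condition and competitor status.
#'
#' @param rate_table A rate table from [build_rate_table()].
#' @param condition Condition to select.
#' @param competitor_present Logical; select S1-alone (`FALSE`) or S1-with-S2
#'   (`TRUE`) trials.
#' @return A tibble with columns `azimuth_deg` (strictly increasing),
#'   `mean_rate_spps`, `sem_spps`, `n_reps`, plus the selecting `condition`
#'   and `competitor_present`. Azimuths with fewer than 2 repetitions get
#'   `NA` SEM and a warning.
#' @export
build_tuning_curve <- function(rate_table, condition = "baseline",
                               competitor_present = FALSE) {
  rows <- dplyr::filter(rate_table,
                        .data$protocol %in% c("loom_single", "loom_pair"),
                        .data$condition == !!condition,
                        .data$competitor_present == !!competitor_present)
  if (dplyr::n_distinct(rows$stimulus_key) < 3) {
    stop("need rates at >= 3 azimuths to build a tuning curve", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(rows, azimuth_deg = .data$stimulus_key),
    mean_rate_spps = mean(.data$evoked_rate_spps),
    sem_spps = stats::sd(.data$evoked_rate_spps) /
      sqrt(dplyr::n()),
    n_reps = dplyr::n(),
    .groups = "drop")
  out <- dplyr::arrange(out, .data$azimuth_deg)
  if (any(out$n_reps < 2)) {
    warning("SEM undefined at azimuth(s) with < 2 repetitions")
  }
  dplyr::mutate(out, condition = condition,
                competitor_present = competitor_present)
}

#' Fit a Gaussian to a tuning curve
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to the per-azimuth mean rates (Levenberg-Marquardt). Initialisation:
#' amplitude = max - min, center = azimuth of the maximum, sigma = half the
#' azimuth span / 2.355 (FWHM heuristic), offset = min; sigma is bounded to
#' `[grid step / 2, span]`. The fit is descriptive; non-convergence returns a
#' result flagged `converged = FALSE` carrying the initialisation values
#' rather than an error.
#'
#' @param curve A tuning curve from [build_tuning_curve()] (needs columns
#'   `azimuth_deg`, `mean_rate_spps`), or any data frame with those columns.
#' @return An object of class `gaussian_fit`: a list with `amplitude`,
#'   `center_deg`, `sigma_deg`, `offset`, `rss`, `converged`, `degenerate`
#'   (amplitude indistinguishable from 0) and `data`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
fit_gaussian <- function(curve) {
  x <- curve$azimuth_deg
  y <- curve$mean_rate_spps
  if (length(x) < 4) stop("need >= 4 points to fit a Gaussian", call. = FALSE)
  span <- diff(range(x))
  step <- min(diff(sort(x)))
  start <- list(amplitude = max(y) - min(y),
                center = x[which.max(y)],
                sigma = (span / 2) / 2.355,
                offset = min(y))
  lower <- c(amplitude = -Inf, center = min(x) - span, sigma = step / 2,
             offset = -Inf)
  upper <- c(amplitude = Inf, center = max(x) + span, sigma = span,
             offset = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-(x - center)^2 / (2 * sigma^2)),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    pars <- unlist(start)
    names(pars) <- c("amplitude", "center", "sigma", "offset")
    rss <- sum((y - (pars["offset"] + pars["amplitude"] *
                       exp(-(x - pars["center"])^2 / (2 * pars["sigma"]^2))))^2)
    converged <- FALSE
  } else {
    pars <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  scale <- max(abs(y), 1e-12)
  out <- list(amplitude = unname(pars["amplitude"]),
              center_deg = unname(pars["center"]),
              sigma_deg = unname(pars["sigma"]),
              offset = unname(pars["offset"]),
              rss = rss,
              converged = converged,
              degenerate = abs(pars["amplitude"]) < 1e-6 * scale ||
                diff(range(y)) < 1e-10 * scale,
              data = tibble::tibble(azimuth_deg = x, mean_rate_spps = y))
  class(out) <- "gaussian_fit"
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("<gaussian_fit>",
      if (!x$converged) "[NOT CONVERGED: initialisation values]",
      if (x$degenerate) "[degenerate: flat curve]", "\n")
  cat(sprintf("  amplitude %.4g sp/s, center %.4g deg, sigma %.4g deg, offset %.4g sp/s\n",
              x$amplitude, x$center_deg, x$sigma_deg, x$offset))
  cat(sprintf("  rss %.6g over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
predict.gaussian_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$azimuth_deg else newdata$azimuth_deg
  object$offset + object$amplitude *
    exp(-(x - object$center_deg)^2 / (2 * object$sigma_deg^2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "center_deg", "sigma_deg", "offset"),
    estimate = c(x$amplitude, x$center_deg, x$sigma_deg, x$offset))
}

#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), converged = x$converged,
                 degenerate = x$degenerate)
}

#' Estimate the spatial receptive field from single-stimulus rates
#'
#' An azimuth is in the receptive field iff (i) its per-repetition evoked
#' rates exceed zero by a one-sided Wilcoxon signed-rank test at `alpha`, and
#' (ii) it lies in the contiguous run of significant azimuths containing the
#' peak-response azimuth (contiguity suppresses spurious isolated locations).
#' The RF centre is the azimuth of maximum mean rate.
#'
#' @param rate_table A rate table; only `loom_single` rows of the chosen
#'   condition are used.
#' @param condition Condition on which to estimate the RF.
#' @param alpha Per-location significance level.
#' @return An object of class `rf_estimate`: a tibble with one row per tested
#'   azimuth (`azimuth_deg`, `mean_rate_spps`, `p_value`, `significant`,
#'   `in_rf`) with attributes `rf_center_az` and `in_rf_azimuths`. Errors with
#'   "no RF detected" if no azimuth is significant.
#' @export
estimate_rf <- function(rate_table, condition = "baseline", alpha = 0.05) {
  rows <- dplyr::filter(rate_table, .data$protocol == "loom_single",
                        .data$condition == !!condition)
  if (nrow(rows) == 0) stop("no single-stimulus rates available", call. = FALSE)
  by_az <- split(rows$evoked_rate_spps, rows$stimulus_key)
  az <- as.numeric(names(by_az))
  ord <- order(az)
  az <- az[ord]
  by_az <- by_az[ord]
  p <- vapply(by_az, function(r) {
    if (all(r == 0)) return(1)
    suppressWarnings(
      stats::wilcox.test(r, mu = 0, alternative = "greater")$p.value)
  }, numeric(1))
  means <- vapply(by_az, mean, numeric(1))
  sig <- p < alpha
  if (!any(sig)) stop("no RF detected", call. = FALSE)
  peak <- which.max(means)
  if (!sig[peak]) {
    # peak not itself significant: use the most significant azimuth's run
    peak <- which.min(p)
  }
  in_rf <- logical(length(az))
  i <- peak
  while (i >= 1 && sig[i]) { in_rf[i] <- TRUE; i <- i - 1 }
  i <- peak
  while (i <= length(az) && sig[i]) { in_rf[i] <- TRUE; i <- i + 1 }

  out <- tibble::tibble(azimuth_deg = az, mean_rate_spps = unname(means),
                        p_value = unname(p), significant = unname(sig),
                        in_rf = in_rf)
  attr(out, "rf_center_az") <- az[which.max(means)]
  attr(out, "in_rf_azimuths") <- az[in_rf]
  class(out) <- c("rf_estimate", class(out))
  out
}

#' In-RF azimuths of an RF estimate
#' @param rf An `rf_estimate` from [estimate_rf()].
#' @return Numeric vector of azimuths inside the receptive field.
#' @export
in_rf_azimuths <- function(rf) attr(rf, "in_rf_azimuths")

#' RF centre azimuth of an RF estimate
#' @param rf An `rf_estimate` from [estimate_rf()].
#' @return Azimuth (deg) of the maximum mean response.
#' @export
rf_center_az <- function(rf) attr(rf, "rf_center_az")

`%||%` <- function(a, b) if (is.null(a)) b else a
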