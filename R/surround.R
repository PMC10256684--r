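#' Suppression index of a bar-length response profile
#'
#' SI = (peak - asymptote) / peak, where the peak is the maximum of the mean
#' rates and the asymptote is the mean response to the three widest bars.
#' Smaller SI means a weaker classical inhibitory surround. The index is
#' invariant to multiplicative rescaling of the whole profile (and therefore
#' to response run-down). SI is not clipped: negative asymptotes (possible
#' after baseline subtraction) can push it above 1; such values are returned
#' as-is. If the peak is not positive the SI is undefined and `NA` is
#' returned with a warning.
#'
#' @param x Either a numeric vector of mean rates (with `lengths_deg` giving
#'   the matching bar lengths) or a profile data frame with columns
#'   `bar_length_deg`/`lengths_deg` and `mean_rate_spps`.
#' @param lengths_deg Bar lengths (deg) matching `x` when `x` is numeric.
#' @return The suppression index (dimensionless scalar), or `NA` if undefined.
#' @examples
#' suppression_index(c(60, 100, 44, 42, 40), c(2, 8, 16, 24, 40))
#' @export
suppression_index <- function(x, lengths_deg = NULL) {
  if (is.data.frame(x)) {
    lcol <- intersect(c("bar_length_deg", "lengths_deg", "stimulus_key"),
                      names(x))[1]
    stopifnot(!is.na(lcol), "mean_rate_spps" %in% names(x))
    lengths_deg <- x[[lcol]]
    x <- x$mean_rate_spps
  }
  stopifnot(is.numeric(x), length(x) == length(lengths_deg))
  if (length(unique(lengths_deg)) < 4) {
    stop("suppression index needs >= 4 distinct bar lengths", call. = FALSE)
  }
  ord <- order(lengths_deg)
  x <- x[ord]
  peak <- max(x)
  if (peak <= 0) {
    warning("peak response <= 0: suppression index undefined")
    return(NA_real_)
  }
  asym <- mean(utils::tail(x, 3))
  (peak - asym) / peak
}

#' Bar-length response profile for one condition
#'
#' Per-length mean and SEM of the evoked rates, with the peak, asymptote
#' (mean of the three widest lengths' means) and suppression index attached
#' as attributes.
#'
#' @param rate_table A rate table from [build_rate_table()].
#' @param condition Condition to select.
#' @return A tibble of class `bar_profile` with columns `bar_length_deg`
#'   (sorted), `mean_rate_spps`, `sem_spps`, `n_reps`, `condition`, and
#'   attributes `peak_rate`, `asymptote_rate`, `si`.
#' @export
bar_length_profile <- function(rate_table, condition = "baseline") {
  rows <- dplyr::filter(rate_table, .data$protocol == "bar",
                        .data$condition == !!condition)
  if (nrow(rows) == 0) stop("no bar trials for condition ", condition,
                            call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(rows, bar_length_deg = .data$stimulus_key),
    mean_rate_spps = mean(.data$evoked_rate_spps),
    sem_spps = stats::sd(.data$evoked_rate_spps) / sqrt(dplyr::n()),
    n_reps = dplyr::n(),
    .groups = "drop")
  out <- dplyr::arrange(out, .data$bar_length_deg)
  out$condition <- condition
  attr(out, "peak_rate") <- max(out$mean_rate_spps)
  attr(out, "asymptote_rate") <- mean(utils::tail(out$mean_rate_spps, 3))
  attr(out, "si") <- suppressWarnings(
    suppression_index(out$mean_rate_spps, out$bar_length_deg))
  class(out) <- c("bar_profile", class(out))
  out
}

#' Normalise a bar-length profile to its peak
#'
#' Divides means and SEMs by the peak mean rate so the maximum becomes 1.
#' The suppression index is unchanged by construction.
#'
#' @param profile A `bar_profile` from [bar_length_profile()].
#' @return The profile with rescaled `mean_rate_spps`/`sem_spps` and updated
#'   attributes.
#' @export
peak_normalize <- function(profile) {
  peak <- max(profile$mean_rate_spps)
  if (peak <= 0) stop("cannot peak-normalise: peak response <= 0",
                      call. = FALSE)
  profile$mean_rate_spps <- profile$mean_rate_spps / peak
  if ("sem_spps" %in% names(profile)) {
    profile$sem_spps <- profile$sem_spps / peak
  }
  attr(profile, "peak_rate") <- 1
  attr(profile, "asymptote_rate") <- mean(utils::tail(profile$mean_rate_spps, 3))
  attr(profile, "si") <- suppressWarnings(
    suppression_index(profile$mean_rate_spps, profile$bar_length_deg))
  profile
}

#' Competitive-suppression scatter for one condition
#'
#' Pairs, per in-RF azimuth, the mean evoked rate to S1 alone (x) with the
#' mean rate to S1 presented together with the distant competitor S2 (y).
#' The fitted line's slope (see [competition_slope()]) quantifies the
#' extraclassical surround: slope 1 means no competitive suppression, smaller
#' slopes mean stronger suppression.
#'
#' @param rate_table A rate table containing both `loom_single` and
#'   `loom_pair` rows for `condition`.
#' @param in_rf_azimuths Azimuths (deg) inside the site's RF, e.g. from
#'   [estimate_rf()]; the fit is restricted to these.
#' @param condition Condition to select.
#' @return A tibble with one row per in-RF azimuth: `azimuth_deg`,
#'   `rate_s1_alone`, `rate_s1_with_s2`, `n_reps_alone`, `n_reps_pair`,
#'   `condition`.
#' @export
competition_scatter <- function(rate_table, in_rf_azimuths,
                                condition = "baseline") {
  rows <- dplyr::filter(rate_table,
                        .data$protocol %in% c("loom_single", "loom_pair"),
                        .data$condition == !!condition,
                        .data$stimulus_key %in% in_rf_azimuths)
  means <- dplyr::summarise(
    dplyr::group_by(rows, azimuth_deg = .data$stimulus_key,
                    competitor = .data$competitor_present),
    mean_rate = mean(.data$evoked_rate_spps), n = dplyr::n(),
    .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "competitor",
                             values_from = c("mean_rate", "n"))
  if (!all(c("mean_rate_FALSE", "mean_rate_TRUE") %in% names(wide))) {
    stop("need both S1-alone and S1-with-S2 rates at shared azimuths",
         call. = FALSE)
  }
  out <- tibble::tibble(
    azimuth_deg = wide$azimuth_deg,
    rate_s1_alone = wide$mean_rate_FALSE,
    rate_s1_with_s2 = wide$mean_rate_TRUE,
    n_reps_alone = wide$n_FALSE,
    n_reps_pair = wide$n_TRUE,
    condition = condition)
  dplyr::arrange(stats::na.omit(out), .data$azimuth_deg)
}

#' Competitive-suppression slope
#'
#' Ordinary least squares fit, with free intercept, of the per-azimuth mean
#' rates to S1-with-S2 against the rates to S1 alone:
#' `rate_s1_with_s2 = slope * rate_s1_alone + intercept`. Needs at least 3
#' in-RF points with non-zero variance in x; otherwise the slope is undefined
#' and the result is flagged.
#'
#' @param scatter A scatter tibble from [competition_scatter()], or any data
#'   frame with columns `rate_s1_alone`, `rate_s1_with_s2`.
#' @return A one-row tibble: `slope`, `intercept`, `n_points`, `flag`
#'   (`NA_character_` when valid; otherwise the reason the slope is
#'   undefined, with slope/intercept `NA`).
#' @examples
#' competition_slope(data.frame(rate_s1_alone = 1:5,
#'                              rate_s1_with_s2 = 0.5 * (1:5)))
#' @export
competition_slope <- function(scatter) {
  x <- scatter$rate_s1_alone
  y <- scatter$rate_s1_with_s2
  n <- length(x)
  if (n < 3) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          n_points = n, flag = "fewer than 3 in-RF points"))
  }
  if (stats::var(x) == 0) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          n_points = n, flag = "zero variance in S1-alone rates"))
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = n, flag = NA_character_)
}
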