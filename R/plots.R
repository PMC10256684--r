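#' Plot a spatial tuning curve
#'
#' Mean +/- SEM evoked rate against azimuth, optionally overlaid with a
#' Gaussian fit.
#'
#' @param curve A tuning curve from [build_tuning_curve()] (or several row-bound
#'   curves distinguished by `condition`/`competitor_present`).
#' @param fit Optional `gaussian_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(curve, fit = NULL) {
  grp <- interaction(curve$condition, curve$competitor_present)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$azimuth_deg,
                                           y = .data$mean_rate_spps,
                                           colour = grp, group = grp)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rate_spps - .data$sem_spps,
      ymax = .data$mean_rate_spps + .data$sem_spps)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Azimuth (deg)", y = "Evoked rate (sp/s)",
                  colour = "condition.competitor") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(curve$azimuth_deg), max(curve$azimuth_deg), length.out = 200)
    fitted <- tibble::tibble(azimuth_deg = xs,
                             mean_rate_spps = predict(fit,
                                                      tibble::tibble(azimuth_deg = xs)))
    p <- p + ggplot2::geom_line(data = fitted, inherit.aes = FALSE,
                                ggplot2::aes(x = .data$azimuth_deg,
                                             y = .data$mean_rate_spps),
                                linetype = 2)
  }
  p
}

#' Plot a bar-length response profile
#'
#' Mean +/- SEM evoked rate against bar length; the asymptote (mean of the
#' three widest lengths) is drawn as a dashed line and the suppression index
#' annotated.
#'
#' @param profile A `bar_profile` (or row-bound profiles across conditions).
#' @return A ggplot object.
#' @export
plot_bar_profile <- function(profile) {
  si <- attr(profile, "si")
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$bar_length_deg,
                                             y = .data$mean_rate_spps,
                                             colour = .data$condition,
                                             group = .data$condition)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rate_spps - .data$sem_spps,
      ymax = .data$mean_rate_spps + .data$sem_spps)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Bar length (deg)", y = "Evoked rate (sp/s)",
                  subtitle = if (!is.null(si) && is.finite(si)) {
                    sprintf("suppression index = %.3f", si)
                  }) +
    ggplot2::theme_minimal()
  if (!is.null(attr(profile, "asymptote_rate"))) {
    p <- p + ggplot2::geom_hline(yintercept = attr(profile, "asymptote_rate"),
                                 linetype = 3)
  }
  p
}

#' Plot a competitive-suppression scatter
#'
#' Per-azimuth mean rate to S1-with-S2 against S1 alone, with the OLS fit and
#' the identity line (slope 1 = no competition).
#'
#' @param scatter A scatter from [competition_scatter()] (or row-bound
#'   scatters across conditions).
#' @return A ggplot object.
#' @export
plot_competition_scatter <- function(scatter) {
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$rate_s1_alone,
                                        y = .data$rate_s1_with_s2,
                                        colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "Rate, S1 alone (sp/s)", y = "Rate, S1 with S2 (sp/s)") +
    ggplot2::theme_minimal()
}

#' @method autoplot bar_profile
#' @export
autoplot.bar_profile <- function(object, ...) plot_bar_profile(object)

#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = paste("null", object$statistic_name),
                  subtitle = sprintf("observed = %.3g, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
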