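#' Simulator configuration
#'
#' Builds a validated configuration for the synthetic spiking-session
#' generator. The generative model is a one-dimensional difference-of-Gaussians
#' (DoG) receptive field — a strong, narrow excitatory centre and a weaker,
#' broader inhibitory surround — driving Poisson spiking, with divisive
#' suppression by a distant competitor stimulus, hard drug-condition switches,
#' and a progressive multiplicative run-down of evoked rates across
#' serially-recorded conditions.
#'
#' @param amp_exc Amplitude of the excitatory centre (sp/s).
#' @param sigma_exc Width (SD, deg) of the excitatory centre.
#' @param amp_inh Amplitude of the inhibitory surround (sp/s). Must satisfy
#'   `amp_exc > amp_inh >= 0`.
#' @param sigma_inh Width (SD, deg) of the inhibitory surround. Must exceed
#'   `sigma_exc`.
#' @param rf_center_az,rf_center_el Receptive-field centre (deg, azimuth and
#'   elevation).
#' @param spont_rate Spontaneous firing rate (sp/s), present throughout the
#'   trial epoch including the pre-onset segment.
#' @param competition_gain_baseline Multiplicative gain `g` in `[0, 1.05]`
#'   applied to in-RF responses when a distant competitor is present, in the
#'   baseline and recovery conditions. `g = 1` means no competition.
#' @param competition_gain_drug Competition gain under the drug condition
#'   (e.g. near 1 under local GABA-A blockade, which releases the site from
#'   competitive suppression).
#' @param surround_scale_drug Multiplier on `amp_inh` under the drug
#'   condition. Use values `< 1` for manipulations that weaken the classical
#'   surround (GABA-A blockade at the input layer); the default 1 models
#'   manipulations that leave the classical surround intact.
#' @param rundown_per_condition Multiplicative rate factor in `(0, 1]`
#'   applied once per condition step (baseline -> drug -> recovery), modelling
#'   slow response run-down over long recordings.
#' @param n_reps Stimulus repetitions per condition (default 15).
#' @param duration_ms Stimulus duration (ms).
#' @param latency_ms Response-onset latency (ms); evoked spikes occupy
#'   `[latency_ms, latency_ms + duration_ms]`.
#' @param pre_onset_ms Length of the pre-onset baseline segment (ms); must be
#'   positive and is 200 by default.
#' @param region Recorded region, `"Imc"` or `"OT10"`; selects default count
#'   windows downstream.
#' @param site_id Identifier used for generated trials.
#' @param azimuth_step,n_azimuths Azimuth grid for loom protocols: `n_azimuths`
#'   locations spaced `azimuth_step` deg, centred on `rf_center_az`.
#' @param bar_lengths Bar lengths (deg) presented in the bar-length protocol.
#' @param s2_offset_deg Azimuthal offset of the competitor S2 from the RF
#'   centre (deg); must be larger than 30 in paired-site scenarios.
#' @param s1_loom_speed,s2_loom_speed Loom speeds (deg/s) of S1 and S2.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(amp_exc = 100, sigma_exc = 2, amp_inh = 60, sigma_inh = 8)
#' bar_response_mean(20, cfg, "baseline")
#' @export
sim_config <- function(amp_exc = 100,
                       sigma_exc = 2,
                       amp_inh = 60,
                       sigma_inh = 8,
                       rf_center_az = 0,
                       rf_center_el = 0,
                       spont_rate = 8,
                       competition_gain_baseline = 0.6,
                       competition_gain_drug = 0.95,
                       surround_scale_drug = 1,
                       rundown_per_condition = 0.9,
                       n_reps = 15,
                       duration_ms = 250,
                       latency_ms = 50,
                       pre_onset_ms = 200,
                       region = c("Imc", "OT10"),
                       site_id = "sim_site",
                       azimuth_step = 5,
                       n_azimuths = 11,
                       bar_lengths = c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 40),
                       s2_offset_deg = 34,
                       s1_loom_speed = 6,
                       s2_loom_speed = 10) {
  region <- match.arg(region)
  cfg <- list(
    amp_exc = amp_exc, sigma_exc = sigma_exc,
    amp_inh = amp_inh, sigma_inh = sigma_inh,
    rf_center_az = rf_center_az, rf_center_el = rf_center_el,
    spont_rate = spont_rate,
    competition_gain_baseline = competition_gain_baseline,
    competition_gain_drug = competition_gain_drug,
    surround_scale_drug = surround_scale_drug,
    rundown_per_condition = rundown_per_condition,
    n_reps = n_reps, duration_ms = duration_ms,
    latency_ms = latency_ms, pre_onset_ms = pre_onset_ms,
    region = region, site_id = site_id,
    azimuth_step = azimuth_step, n_azimuths = n_azimuths,
    bar_lengths = sort(bar_lengths),
    s2_offset_deg = s2_offset_deg,
    s1_loom_speed = s1_loom_speed, s2_loom_speed = s2_loom_speed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num <- cfg[vapply(cfg, is.numeric, logical(1))]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    stop("sim_config: all numeric fields must be finite", call. = FALSE)
  }
  stopifnot(
    "sigma_inh must exceed sigma_exc (> 0)" =
      cfg$sigma_inh > cfg$sigma_exc && cfg$sigma_exc > 0,
    "need amp_exc > amp_inh >= 0" =
      cfg$amp_exc > cfg$amp_inh && cfg$amp_inh >= 0,
    "competition gains must lie in [0, 1.05]" =
      cfg$competition_gain_baseline >= 0 && cfg$competition_gain_baseline <= 1.05 &&
        cfg$competition_gain_drug >= 0 && cfg$competition_gain_drug <= 1.05,
    "rundown_per_condition must lie in (0, 1]" =
      cfg$rundown_per_condition > 0 && cfg$rundown_per_condition <= 1,
    "spont_rate must be non-negative" = cfg$spont_rate >= 0,
    "n_reps must be a positive integer" = cfg$n_reps >= 1,
    "pre_onset_ms must be positive and fit within a 1500 ms ISI" =
      cfg$pre_onset_ms > 0 && cfg$pre_onset_ms <= 1500,
    "need at least 4 bar lengths" = length(cfg$bar_lengths) >= 4,
    "n_azimuths must be >= 3" = cfg$n_azimuths >= 3
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$region, "site", shQuote(x$site_id), "\n")
  cat(sprintf("  DoG: amp_exc %g (sigma %g deg), amp_inh %g (sigma %g deg)\n",
              x$amp_exc, x$sigma_exc, x$amp_inh, x$sigma_inh))
  cat(sprintf("  RF centre: (%g, %g) deg; spont %g sp/s\n",
              x$rf_center_az, x$rf_center_el, x$spont_rate))
  cat(sprintf("  competition gain: %g (baseline) / %g (drug); surround scale (drug): %g\n",
              x$competition_gain_baseline, x$competition_gain_drug,
              x$surround_scale_drug))
  cat(sprintf("  rundown/condition: %g; %d reps x %g ms\n",
              x$rundown_per_condition, x$n_reps, x$duration_ms))
  invisible(x)
}

#' Modify a simulator configuration
#'
#' Returns a copy of `cfg` with the named fields replaced and the result
#' re-validated.
#'
#' @param cfg A [sim_config()].
#' @param ... Named fields to replace.
#' @return A `sim_config`.
#' @export
update_sim_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(unclass(cfg)))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
}

#' Read a simulator configuration from YAML
#'
#' The YAML file holds a flat mapping of [sim_config()] fields; missing fields
#' take the package defaults. An optional `windows` block (region -> protocol
#' -> `[start, end]` in ms) is parsed with [read_window_policy()] and attached
#' as the `"window_policy"` attribute.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`, possibly with a `"window_policy"` attribute.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  wp <- NULL
  if (!is.null(y$windows)) {
    wp <- read_window_policy(y$windows)
    y$windows <- NULL
  }
  keep <- intersect(names(y), names(formals(sim_config)))
  cfg <- do.call(sim_config, y[keep])
  if (!is.null(wp)) attr(cfg, "window_policy") <- wp
  cfg
}
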