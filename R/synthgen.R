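#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

conditions_order <- c("baseline", "drug", "recovery")

check_condition <- function(condition) {
  if (!all(condition %in% conditions_order)) {
    stop("condition must be one of: ", paste(conditions_order, collapse = ", "),
         call. = FALSE)
  }
  condition
}

#' Run-down factor for a condition
#'
#' Conditions are recorded serially (baseline, then drug, then recovery), and
#' evoked rates decline multiplicatively by `rundown_per_condition` at each
#' step.
#'
#' @param config A [sim_config()].
#' @param condition `"baseline"`, `"drug"` or `"recovery"` (vectorised).
#' @return Multiplicative factor(s) in `(0, 1]`.
#' @export
rundown_factor <- function(config, condition) {
  check_condition(condition)
  config$rundown_per_condition^(match(condition, conditions_order) - 1)
}

#' Expected evoked rate for a bar of given length
#'
#' The bar-length response profile of a centre-surround receptive field:
#' a centred bar of length `L` covers a fraction
#' `Phi(L; sigma) = erf(L / (2 * sqrt(2) * sigma))` of the mass of each
#' Gaussian RF component, so the expected evoked rate is
#' `rundown * (amp_exc * Phi(L; sigma_exc) - amp_inh_eff * Phi(L; sigma_inh))`,
#' clipped at zero. Short bars drive mostly the narrow excitatory centre
#' (rising phase); longer bars recruit progressively more of the broad
#' inhibitory surround (falling phase) until both saturate (asymptote
#' `amp_exc - amp_inh_eff`). Under the drug condition the surround amplitude
#' is scaled by `surround_scale_drug`.
#'
#' @param length_deg Bar length(s), deg; must be non-negative.
#' @param config A [sim_config()].
#' @param condition Condition label; sets the run-down factor and the
#'   effective surround amplitude.
#' @return Expected evoked firing rate(s), sp/s.
#' @examples
#' cfg <- sim_config()
#' bar_response_mean(c(2, 8, 40), cfg, "baseline")
#' @export
bar_response_mean <- function(length_deg, config, condition = "baseline") {
  stopifnot(inherits(config, "sim_config"))
  check_condition(condition)
  if (any(!is.finite(length_deg)) || any(length_deg < 0)) {
    stop("length_deg must be finite and non-negative", call. = FALSE)
  }
  amp_inh_eff <- config$amp_inh *
    ifelse(condition == "drug", config$surround_scale_drug, 1)
  phi_e <- erf(length_deg / (2 * sqrt(2) * config$sigma_exc))
  phi_i <- erf(length_deg / (2 * sqrt(2) * config$sigma_inh))
  pmax(0, rundown_factor(config, condition) *
         (config$amp_exc * phi_e - amp_inh_eff * phi_i))
}

#' Expected evoked rate for a looming stimulus at a given azimuth
#'
#' Spatial tuning is Gaussian around the RF centre. When a distant competitor
#' (S2) is present, the response is divisively suppressed: it is multiplied by
#' the condition-appropriate competition gain (`competition_gain_baseline` in
#' baseline/recovery, `competition_gain_drug` under the drug).
#'
#' @param azimuth_deg Stimulus azimuth(s), deg.
#' @param config A [sim_config()].
#' @param competitor_present Logical; is the distant S2 present?
#' @param condition Condition label.
#' @return Expected evoked firing rate(s), sp/s.
#' @export
loom_tuning_mean <- function(azimuth_deg, config, competitor_present = FALSE,
                             condition = "baseline") {
  stopifnot(inherits(config, "sim_config"))
  check_condition(condition)
  if (any(!is.finite(azimuth_deg))) stop("azimuth_deg must be finite", call. = FALSE)
  base <- rundown_factor(config, condition) * config$amp_exc *
    exp(-(azimuth_deg - config$rf_center_az)^2 / (2 * config$sigma_exc^2))
  g <- ifelse(condition == "drug",
              config$competition_gain_drug, config$competition_gain_baseline)
  pmax(0, base * ifelse(competitor_present, g, 1))
}

#' Expected evoked rate for any trial description
#' @keywords internal
expected_rate <- function(config, protocol, stimulus, competitor, condition) {
  out <- numeric(length(protocol))
  is_bar <- protocol == "bar"
  if (any(is_bar)) {
    out[is_bar] <- bar_response_mean(stimulus[is_bar], config,
                                     condition = condition[is_bar])
  }
  if (any(!is_bar)) {
    out[!is_bar] <- loom_tuning_mean(stimulus[!is_bar], config,
                                     competitor_present = competitor[!is_bar],
                                     condition = condition[!is_bar])
  }
  out
}

azimuth_grid <- function(config) {
  half <- (config$n_azimuths - 1) / 2
  config$rf_center_az + config$azimuth_step * seq(-half, half)
}

stimulus_plan <- function(config, protocols) {
  plans <- list()
  if ("loom_single" %in% protocols) {
    plans$loom_single <- tibble::tibble(protocol = "loom_single",
                                        stimulus = azimuth_grid(config),
                                        competitor = FALSE)
  }
  if ("loom_pair" %in% protocols) {
    plans$loom_pair <- tibble::tibble(protocol = "loom_pair",
                                      stimulus = azimuth_grid(config),
                                      competitor = TRUE)
  }
  if ("bar" %in% protocols) {
    plans$bar <- tibble::tibble(protocol = "bar",
                                stimulus = config$bar_lengths,
                                competitor = FALSE)
  }
  dplyr::bind_rows(plans)
}

#' Simulate a full spiking session for one site
#'
#' Generates a trial table with spike times for every stimulus value x
#' repetition x condition. For each trial the evoked spike count is drawn as
#' Poisson(expected rate x stimulus duration) and the spikes are placed
#' uniformly within the response window `[latency, latency + duration]`;
#' spontaneous spikes are drawn as Poisson(`spont_rate`) over the whole trial
#' epoch, which includes a `pre_onset_ms` pre-stimulus segment used downstream
#' for baseline-rate estimation. Trial order is randomly interleaved within
#' each condition (conditions themselves are serial, as in iontophoresis
#' experiments). Only spike counts within analysis windows matter downstream,
#' so no temporal microstructure beyond this is modelled.
#'
#' @param config A [sim_config()].
#' @param protocols Subset of `c("loom_single", "loom_pair", "bar")`.
#' @param conditions Ordered subset of `c("baseline", "drug", "recovery")`.
#' @param seed Integer seed; identical `(config, seed)` pairs give identical
#'   sessions.
#' @return A tibble with one row per trial: trial/site identifiers, condition,
#'   protocol, stimulus fields, and a `spike_times_ms` list-column of sorted
#'   spike times (ms, 0 = stimulus onset; negative = pre-onset).
#' @examples
#' sess <- simulate_session(sim_config(n_reps = 2), protocols = "bar",
#'                          conditions = "baseline", seed = 1)
#' nrow(sess)
#' @export
simulate_session <- function(config,
                             protocols = c("loom_single", "loom_pair", "bar"),
                             conditions = c("baseline", "drug", "recovery"),
                             seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(protocols) == 0) stop("empty protocol set", call. = FALSE)
  protocols <- match.arg(protocols, several.ok = TRUE)
  conditions <- conditions_order[conditions_order %in% check_condition(conditions)]

  withr::with_seed(as.integer(seed), {
    plan <- stimulus_plan(config, protocols)
    trials <- purrr::map(conditions, function(cond) {
      tr <- tidyr::expand_grid(plan, repetition = seq_len(config$n_reps))
      tr <- tr[sample.int(nrow(tr)), ]           # pseudo-random interleaving
      tr$condition <- cond
      tr
    })
    trials <- dplyr::bind_rows(trials)
    trials$order_in_session <- seq_len(nrow(trials))

    mu <- expected_rate(config, trials$protocol, trials$stimulus,
                        trials$competitor, trials$condition)
    dur_s <- config$duration_ms / 1000
    epoch <- c(-config$pre_onset_ms,
               config$latency_ms + config$duration_ms + 100)
    epoch_s <- diff(epoch) / 1000
    n <- nrow(trials)
    n_evoked <- stats::rpois(n, mu * dur_s)
    n_spont <- stats::rpois(n, config$spont_rate * epoch_s)
    spikes <- purrr::map(seq_len(n), function(i) {
      ev <- stats::runif(n_evoked[i], config$latency_ms,
                         config$latency_ms + config$duration_ms)
      sp <- stats::runif(n_spont[i], epoch[1], epoch[2])
      sort(c(ev, sp))
    })

    tibble::tibble(
      site_id = config$site_id,
      trial_id = sprintf("%s_t%05d", config$site_id, trials$order_in_session),
      condition = trials$condition,
      protocol = trials$protocol,
      s1_azimuth_deg = ifelse(trials$protocol == "bar",
                              config$rf_center_az, trials$stimulus),
      s1_elevation_deg = config$rf_center_el,
      s1_loom_speed_dps = ifelse(trials$protocol == "bar", NA_real_,
                                 config$s1_loom_speed),
      s2_azimuth_deg = ifelse(trials$competitor,
                              config$rf_center_az + config$s2_offset_deg,
                              NA_real_),
      s2_elevation_deg = ifelse(trials$competitor, config$rf_center_el,
                                NA_real_),
      s2_loom_speed_dps = ifelse(trials$competitor, config$s2_loom_speed,
                                 NA_real_),
      bar_length_deg = ifelse(trials$protocol == "bar", trials$stimulus,
                              NA_real_),
      bar_height_deg = ifelse(trials$protocol == "bar", 3, NA_real_),
      duration_ms = config$duration_ms,
      repetition = trials$repetition,
      region = config$region,
      rf_center_az_deg = config$rf_center_az,
      rf_center_el_deg = config$rf_center_el,
      contralateral_positive = TRUE,
      spike_times_ms = spikes
    )
  })
}

#' Simulate per-repetition evoked rates directly (fast path)
#'
#' Draws the same spike-count statistics as [simulate_session()] followed by
#' [build_rate_table()], without materialising spike times: the count in the
#' analysis window of length `w` is Poisson((mu + spont) * w), the baseline
#' count is Poisson(spont * b), and the evoked rate is the difference of the
#' two window rates. Used for large resampling studies where only window
#' counts matter.
#'
#' @inheritParams simulate_session
#' @param window_policy A window-policy tibble, see [default_window_policy()].
#' @return A rate table, as from [build_rate_table()].
#' @export
simulate_rate_table <- function(config,
                                protocols = c("loom_single", "loom_pair", "bar"),
                                conditions = c("baseline", "drug", "recovery"),
                                seed = 1L,
                                window_policy = default_window_policy()) {
  stopifnot(inherits(config, "sim_config"))
  protocols <- match.arg(protocols, several.ok = TRUE)
  conditions <- conditions_order[conditions_order %in% check_condition(conditions)]

  withr::with_seed(as.integer(seed), {
    plan <- stimulus_plan(config, protocols)
    tab <- tidyr::expand_grid(condition = conditions, plan,
                              repetition = seq_len(config$n_reps))
    win <- lookup_windows(window_policy, config$region, tab$protocol)
    w_s <- (win$end - win$start) / 1000
    b_s <- config$pre_onset_ms / 1000
    mu <- expected_rate(config, tab$protocol, tab$stimulus,
                        tab$competitor, tab$condition)
    counts <- stats::rpois(nrow(tab), (mu + config$spont_rate) * w_s)
    base <- stats::rpois(nrow(tab), config$spont_rate * b_s)
    tibble::tibble(
      site_id = config$site_id,
      region = config$region,
      condition = tab$condition,
      protocol = tab$protocol,
      stimulus_key = tab$stimulus,
      competitor_present = tab$competitor,
      repetition_index = tab$repetition,
      evoked_rate_spps = counts / w_s - base / b_s
    )
  })
}

#' Simulate a paired-site recording
#'
#' Generates sessions for two simultaneously recorded sites under one of the
#' paired experimental designs:
#'
#' * `"ot10_imc"` — spatially aligned OT10 (site A, drugged) and Imc (site B)
#'   sites, bar-length protocol. The Imc site's classical surround is
#'   inherited from OT10: site B shares site A's DoG shape and its
#'   `surround_scale_drug`, so GABA-A blockade at OT10 flattens the surround
#'   at both sites.
#' * `"imc_imc"` — distant Imc sites (RF centres > 30 deg apart), loom
#'   protocols at site A. Site B encodes the competitor; silencing it (drug)
#'   sets site A's competition gain to 1 and scales site B's evoked rates
#'   towards zero (`amp_exc` x 0.1).
#' * `"spread_control"` — as `"imc_imc"`, but the drug at site B has no effect
#'   at site A (gain and run-down held constant at site A), modelling absence
#'   of drug spread.
#'
#' @param config_a,config_b [sim_config()]s for the two sites (site ids should
#'   differ; RF centres must be > 30 deg apart for the Imc-Imc scenarios).
#' @param scenario One of `"ot10_imc"`, `"imc_imc"`, `"spread_control"`.
#' @param conditions Ordered subset of the three conditions.
#' @param seed Integer seed.
#' @return A named list of two trial tibbles, `site_a` and `site_b`, with the
#'   effective (post-switch) configurations attached as attributes `config_a`
#'   and `config_b`.
#' @export
simulate_paired_sites <- function(config_a, config_b,
                                  scenario = c("ot10_imc", "imc_imc",
                                               "spread_control"),
                                  conditions = c("baseline", "drug", "recovery"),
                                  seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config_a, "sim_config"), inherits(config_b, "sim_config"))
  seed <- as.integer(seed)

  if (scenario %in% c("imc_imc", "spread_control")) {
    d <- abs(config_a$rf_center_az - config_b$rf_center_az)
    if (d < 30) {
      stop("imc_imc scenarios require RF centres > 30 deg apart (got ",
           round(d, 1), " deg)", call. = FALSE)
    }
  }

  if (scenario == "ot10_imc") {
    # surround inherited: site B takes A's DoG widths, relative surround
    # strength and drug switch; amplitudes stay its own
    config_a <- update_sim_config(config_a, region = "OT10")
    config_b <- update_sim_config(
      config_b, region = "Imc",
      sigma_exc = config_a$sigma_exc, sigma_inh = config_a$sigma_inh,
      amp_inh = config_b$amp_exc * config_a$amp_inh / config_a$amp_exc,
      surround_scale_drug = config_a$surround_scale_drug)
    protocols_a <- protocols_b <- "bar"
  } else {
    # competitor encoded by site B; silencing it releases site A from
    # competitive suppression
    config_a <- update_sim_config(config_a, competition_gain_drug = 1)
    config_b <- update_sim_config(config_b, amp_exc = config_b$amp_exc,
                                  surround_scale_drug = 1)
    protocols_a <- c("loom_single", "loom_pair")
    protocols_b <- "loom_single"
  }
  if (scenario == "spread_control") {
    config_a <- update_sim_config(config_a,
                                  competition_gain_drug =
                                    config_a$competition_gain_baseline,
                                  rundown_per_condition = 1)
  }

  site_a <- simulate_session(config_a, protocols = protocols_a,
                             conditions = conditions, seed = seed)
  site_b <- simulate_session(config_b, protocols = protocols_b,
                             conditions = conditions, seed = seed + 1L)
  if (scenario == "imc_imc") {
    # site B silenced under the drug: rescale its evoked spikes by thinning
    site_b <- thin_evoked(site_b, config_b, factor = 0.1,
                          condition = "drug", seed = seed + 2L)
  }
  # effective (post-switch) configurations, for ground-truth inspection
  structure(list(site_a = site_a, site_b = site_b),
            config_a = config_a, config_b = config_b, scenario = scenario)
}

# Remove evoked (post-onset, response-window) spikes with prob 1 - factor on
# the given condition's trials; models iontophoretic silencing of the site.
thin_evoked <- function(session, config, factor, condition, seed) {
  withr::with_seed(as.integer(seed), {
    lo <- config$latency_ms
    hi <- config$latency_ms + config$duration_ms
    idx <- which(session$condition == condition)
    session$spike_times_ms[idx] <- purrr::map(session$spike_times_ms[idx],
      function(st) {
        in_win <- st >= lo & st <= hi
        keep <- !in_win | stats::runif(length(st)) < factor
        st[keep]
      })
    session
  })
}

#' Ground truth implied by a simulator configuration
#'
#' Derives, per condition, the noise-free values of the two headline
#' statistics: the expected suppression index of the bar-length profile
#' (computed from [bar_response_mean()] at the configured bar lengths, and
#' also in continuous form with the peak found by numerical maximisation and
#' the asymptote taken as the infinite-length limit
#' `rundown * (amp_exc - amp_inh_eff)`), and the expected competition slope,
#' which equals the configured competition gain for that condition exactly.
#'
#' @param config A [sim_config()].
#' @param conditions Conditions to tabulate.
#' @return A tibble with columns `condition`, `expected_si`,
#'   `expected_si_continuous`, `expected_slope`.
#' @export
ground_truth <- function(config, conditions = c("baseline", "drug", "recovery")) {
  stopifnot(inherits(config, "sim_config"))
  check_condition(conditions)
  purrr::map_dfr(conditions, function(cond) {
    prof <- bar_response_mean(config$bar_lengths, config, cond)
    si_grid <- suppression_index(prof, config$bar_lengths)
    peak <- stats::optimize(function(L) bar_response_mean(L, config, cond),
                            c(0, 20 * config$sigma_inh), maximum = TRUE,
                            tol = 1e-10)$objective
    amp_inh_eff <- config$amp_inh *
      if (cond == "drug") config$surround_scale_drug else 1
    asym <- max(0, rundown_factor(config, cond) *
                  (config$amp_exc - amp_inh_eff))
    tibble::tibble(
      condition = cond,
      expected_si = si_grid,
      expected_si_continuous = (peak - asym) / peak,
      expected_slope = if (cond == "drug") config$competition_gain_drug
                       else config$competition_gain_baseline
    )
  })
}
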