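#' Experiment designs
#'
#' The five experiment designs the pipeline orchestrates, with their metric
#' and protocol set:
#'
#' * `imc_gaba_competition` — GABA-A blockade at the recorded Imc site; loom
#'   tuning curves with/without a distant competitor; metric: competition
#'   slope. The drug releases competitive suppression (gain toward 1) but
#'   leaves the classical surround untouched.
#' * `imc_gaba_barlength` — same manipulation, bar-length profiles; metric:
#'   suppression index. The drug does not alter the classical surround.
#' * `ot10_imc_paired` — GABA-A blockade at an OT10 site recorded
#'   simultaneously with a spatially aligned Imc site; bar-length profiles at
#'   both; metric: SI at both sites (the Imc surround is inherited from OT10,
#'   so blockade flattens both).
#' * `imc_imc_paired` — glutamatergic silencing of a distant Imc site (site B)
#'   encoding the competitor while recording site A; metric: competition slope
#'   at site A (silencing site B releases site A from suppression).
#' * `spread_control` — as `imc_imc_paired` but with no drug effect at site A,
#'   to model absence of iontophoresis spread.
#'
#' @return Character vector of design names.
#' @export
experiment_designs <- function() {
  c("imc_gaba_competition", "imc_gaba_barlength", "ot10_imc_paired",
    "imc_imc_paired", "spread_control")
}

#' Metric associated with a design
#' @param design One of [experiment_designs()].
#' @return `"slope"` or `"si"`.
#' @export
metric_for_design <- function(design) {
  design <- match.arg(design, experiment_designs())
  switch(design,
         imc_gaba_competition = "slope",
         imc_gaba_barlength = "si",
         ot10_imc_paired = "si",
         imc_imc_paired = "slope",
         spread_control = "slope")
}

design_is_paired <- function(design) {
  design %in% c("ot10_imc_paired", "imc_imc_paired", "spread_control")
}

#' Default simulator configuration for a design
#'
#' Tuning-curve (loom) designs use a broad excitatory centre (sigma 6 deg,
#' matching the multi-location extent of measured RFs on a 5-degree grid);
#' bar-length designs use the narrow-centre/broad-surround DoG (sigma 2 and
#' 8 deg) that produces the canonical rise-dip-asymptote profile. The
#' OT10-Imc paired design sets `surround_scale_drug = 0.1` (GABA-A blockade
#' at the input layer flattens the classical surround); the single-site GABA
#' designs leave the surround intact (`surround_scale_drug = 1`) and act on
#' the competition gain only.
#'
#' @param design One of [experiment_designs()].
#' @param site_id Site identifier.
#' @return A [sim_config()].
#' @export
default_design_config <- function(design, site_id = "siteA") {
  design <- match.arg(design, experiment_designs())
  switch(design,
    imc_gaba_competition = sim_config(
      sigma_exc = 6, sigma_inh = 18, amp_inh = 40,
      competition_gain_baseline = 0.6, competition_gain_drug = 0.95,
      region = "Imc", site_id = site_id),
    imc_gaba_barlength = sim_config(
      sigma_exc = 2, sigma_inh = 8, amp_inh = 60,
      surround_scale_drug = 1, region = "Imc", site_id = site_id),
    ot10_imc_paired = sim_config(
      sigma_exc = 2, sigma_inh = 8, amp_inh = 60,
      surround_scale_drug = 0.1, region = "OT10", site_id = site_id),
    imc_imc_paired = sim_config(
      sigma_exc = 6, sigma_inh = 18, amp_inh = 40,
      competition_gain_baseline = 0.6, competition_gain_drug = 1,
      region = "Imc", site_id = site_id),
    spread_control = sim_config(
      sigma_exc = 6, sigma_inh = 18, amp_inh = 40,
      competition_gain_baseline = 0.6, region = "Imc", site_id = site_id))
}

# site-to-site heterogeneity applied around a base configuration: response
# amplitudes and spontaneous rates vary log-normally, competition gains
# jitter slightly (truncated to the valid range), RF centres scatter on the
# stimulus grid
jitter_config <- function(base, site_id) {
  g_j <- function(g) max(0, min(1.05, g + stats::rnorm(1, 0, 0.03)))
  # one amplitude scale for centre and surround, so the centre/surround ratio
  # (and hence the noise-free SI) is preserved across sites
  amp_scale <- exp(stats::rnorm(1, 0, 0.15))
  update_sim_config(
    base,
    site_id = site_id,
    amp_exc = base$amp_exc * amp_scale,
    amp_inh = base$amp_inh * amp_scale,
    spont_rate = base$spont_rate * exp(stats::rnorm(1, 0, 0.2)),
    rf_center_az = base$rf_center_az +
      base$azimuth_step * sample(-4:4, 1),
    competition_gain_baseline = g_j(base$competition_gain_baseline),
    competition_gain_drug = g_j(base$competition_gain_drug))
}

#' Simulate a multi-site experiment
#'
#' Draws `n_sites` site configurations around `base_config` (log-normal
#' amplitude/spontaneous-rate variation, small competition-gain jitter,
#' RF-centre scatter) and simulates a session per site (or per site pair for
#' paired designs).
#'
#' @param design One of [experiment_designs()].
#' @param n_sites Number of sites (site pairs for paired designs).
#' @param seed Master integer seed; per-site seeds are derived from it.
#' @param base_config Optional [sim_config()] overriding
#'   [default_design_config()].
#' @param conditions Ordered subset of baseline/drug/recovery.
#' @return A list of class `sim_experiment`: `design`, `conditions`,
#'   `sessions` (per site: a session tibble, or a `list(site_a, site_b)` for
#'   paired designs), `configs`, and `ground_truth` (per-site expected SI and
#'   slope per condition).
#' @export
simulate_experiment <- function(design, n_sites, seed = 1L,
                                base_config = NULL,
                                conditions = c("baseline", "drug")) {
  design <- match.arg(design, experiment_designs())
  base <- base_config %||% default_design_config(design)
  seeds_and_cfgs <- withr::with_seed(as.integer(seed), {
    site_seeds <- sample.int(2^20, n_sites)
    cfgs <- purrr::map(seq_len(n_sites),
                       function(i) jitter_config(base, sprintf("site%03d", i)))
    list(seeds = site_seeds, cfgs = cfgs)
  })
  cfgs <- seeds_and_cfgs$cfgs
  site_seeds <- seeds_and_cfgs$seeds

  paired <- design_is_paired(design)
  scenario <- switch(design, ot10_imc_paired = "ot10_imc",
                     imc_imc_paired = "imc_imc",
                     spread_control = "spread_control", NULL)
  protocols <- if (metric_for_design(design) == "slope") {
    c("loom_single", "loom_pair")
  } else "bar"

  sessions <- purrr::map(seq_len(n_sites), function(i) {
    cfg <- cfgs[[i]]
    if (!paired) {
      simulate_session(cfg, protocols = protocols, conditions = conditions,
                       seed = site_seeds[i])
    } else {
      cfg_b <- update_sim_config(
        cfg, site_id = paste0(cfg$site_id, "b"),
        rf_center_az = cfg$rf_center_az +
          if (scenario == "ot10_imc") 0 else cfg$s2_offset_deg)
      simulate_paired_sites(cfg, cfg_b, scenario = scenario,
                            conditions = conditions, seed = site_seeds[i])
    }
  })
  gt <- purrr::map_dfr(cfgs, function(cfg) {
    dplyr::mutate(ground_truth(cfg, conditions), site_id = cfg$site_id,
                  .before = 1)
  })
  structure(list(design = design, conditions = conditions,
                 sessions = sessions, configs = cfgs, ground_truth = gt),
            class = "sim_experiment")
}

#' Gate a site pair on effective silencing of site B
#'
#' Paired-site analyses are included only when the drug caused a significant
#' reduction of evoked responses at site B: a one-sided rank-sum test
#' (drug < baseline) on the per-repetition rates at site B's peak stimulus.
#'
#' @param rate_table_b Rate table of site B with baseline and drug rows.
#' @param alpha Significance level.
#' @return A list: `include` (logical), `p_value`, `peak_stimulus`.
#' @export
site_pair_gate <- function(rate_table_b, alpha = 0.05) {
  base <- rate_table_b[rate_table_b$condition == "baseline", , drop = FALSE]
  drug <- rate_table_b[rate_table_b$condition == "drug", , drop = FALSE]
  if (nrow(drug) == 0) stop("site B has no drug-condition data", call. = FALSE)
  if (nrow(base) == 0) stop("site B has no baseline data", call. = FALSE)
  mns <- tapply(base$evoked_rate_spps, base$stimulus_key, mean)
  peak <- as.numeric(names(mns))[which.max(mns)]
  x <- drug$evoked_rate_spps[drug$stimulus_key == peak]
  y <- base$evoked_rate_spps[base$stimulus_key == peak]
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less")$p.value)
  list(include = p < alpha, p_value = p, peak_stimulus = peak)
}

# per-site metric values for every condition; returns NULL (with reason) on
# precondition failure rather than erroring the run
site_metric_values <- function(rate_table, metric, conditions, alpha = 0.05) {
  if (metric == "slope") {
    rf <- tryCatch(estimate_rf(rate_table, "baseline", alpha = alpha),
                   error = function(e) conditionMessage(e))
    if (is.character(rf)) return(list(error = rf))
    azs <- in_rf_azimuths(rf)
    if (length(azs) < 3) {
      return(list(error = "fewer than 3 in-RF azimuths"))
    }
    vals <- purrr::map_dbl(conditions, function(cond) {
      competition_slope(competition_scatter(rate_table, azs, cond))$slope
    })
    list(values = stats::setNames(vals, conditions), in_rf = azs)
  } else {
    vals <- purrr::map_dbl(conditions, function(cond) {
      suppressWarnings(
        attr(bar_length_profile(rate_table, cond), "si"))
    })
    if (anyNA(vals)) return(list(error = "peak response <= 0"))
    list(values = stats::setNames(vals, conditions))
  }
}

#' Analyse a (simulated or recorded) multi-site experiment
#'
#' Runs the full per-site and population analysis for one design: evoked-rate
#' extraction, RF estimation (slope designs), per-condition metric values, a
#' per-site repetition-shuffling permutation test (baseline vs drug), the
#' site-B inclusion gate for Imc-Imc pairs, then population statistics on the
#' per-site differences: single-pass outlier removal (median +/- 1.5 IQR),
#' two-sided sign-rank test, and - when all three conditions are present -
#' the three pairwise recovery comparisons with Holm correction.
#'
#' @param sessions A list of session tibbles (or `list(site_a, site_b)` pairs
#'   for paired designs), e.g. from [simulate_experiment()]`$sessions`, or a
#'   `sim_experiment` object itself.
#' @param design One of [experiment_designs()] (taken from the object when a
#'   `sim_experiment` is supplied).
#' @param n_perm Permutations for the per-site tests.
#' @param seed Integer seed for the permutation tests.
#' @param window_policy Count-window policy; see [default_window_policy()].
#' @param alpha Significance level used by the RF estimate and the site-pair
#'   gate.
#' @return An object of class `experiment_result`: a list with `design`,
#'   `metric`, `site_metrics` (long tibble: site, condition, value),
#'   `site_summary` (wide: per-site values, drug - baseline `difference`,
#'   `outlier` flag), `perm_results`, `population_summary` (list), `recovery`
#'   (pairwise table or NULL) and `excluded` (sites with reasons).
#' @export
analyze_experiment <- function(sessions, design = NULL, n_perm = 500,
                               seed = 1L, window_policy = default_window_policy(),
                               alpha = 0.05) {
  if (inherits(sessions, "sim_experiment")) {
    design <- design %||% sessions$design
    sessions <- sessions$sessions
  }
  design <- match.arg(design, experiment_designs())
  metric <- metric_for_design(design)
  paired <- design_is_paired(design)

  per_site <- purrr::imap(sessions, function(sess, i) {
    analyze_one_site_entry(sess, design, metric, paired, n_perm,
                           seed = as.integer(seed) + i,
                           window_policy = window_policy, alpha = alpha)
  })
  excluded <- purrr::map_dfr(per_site, "excluded")
  metrics <- purrr::map_dfr(per_site, "metrics")
  perms <- purrr::map_dfr(per_site, "perm")

  if (nrow(metrics) == 0) {
    stop("no analysable sites (all excluded): ",
         paste(unique(excluded$reason), collapse = "; "), call. = FALSE)
  }
  conditions <- intersect(conditions_order, unique(metrics$condition))
  wide <- tidyr::pivot_wider(metrics, names_from = "condition",
                             values_from = "value", names_prefix = "value_")
  if (all(c("value_baseline", "value_drug") %in% names(wide))) {
    wide$difference <- wide$value_drug - wide$value_baseline
  } else {
    wide$difference <- NA_real_
  }

  pop <- population_summary(wide, metric, conditions)
  wide$outlier <- FALSE
  if (!is.null(pop$outlier_indices) && length(pop$outlier_indices)) {
    wide$outlier[pop$outlier_indices] <- TRUE
  }
  recov <- NULL
  if (all(paste0("value_", conditions_order) %in% names(wide))) {
    recov <- recovery_report(wide, metric = metric)
  }
  structure(list(design = design, metric = metric,
                 site_metrics = metrics, site_summary = wide,
                 perm_results = perms, population_summary = pop,
                 recovery = recov, excluded = excluded,
                 n_perm = n_perm, seed = seed),
            class = "experiment_result")
}

analyze_one_site_entry <- function(sess, design, metric, paired, n_perm, seed,
                                   window_policy, alpha) {
  empty <- list(metrics = NULL, perm = NULL,
                excluded = tibble::tibble(site_id = character(0),
                                          reason = character(0)))
  exclude <- function(id, reason) {
    out <- empty
    out$excluded <- tibble::tibble(site_id = id, reason = reason)
    out
  }
  entries <- if (paired) sess else list(site_a = sess)
  rt_a <- build_rate_table(entries$site_a, window_policy = window_policy)
  site_a_id <- rt_a$site_id[1]
  conditions <- intersect(conditions_order, unique(rt_a$condition))

  if (design == "imc_imc_paired") {
    rt_b <- build_rate_table(entries$site_b, window_policy = window_policy)
    gate <- site_pair_gate(rt_b, alpha = alpha)
    if (!gate$include) {
      return(exclude(site_a_id, "site B not significantly silenced by drug"))
    }
  }

  analyze_site <- function(rt) {
    id <- rt$site_id[1]
    sm <- site_metric_values(rt, metric, conditions, alpha = alpha)
    if (!is.null(sm$error)) return(exclude(id, sm$error))
    pt <- NULL
    if (all(c("baseline", "drug") %in% conditions)) {
      pt <- if (metric == "slope") {
        perm_test_slope(rt, sm$in_rf, "baseline", "drug",
                        n_perm = n_perm, seed = seed)
      } else {
        perm_test_si(rt, "baseline", "drug", n_perm = n_perm, seed = seed)
      }
    }
    list(metrics = tibble::tibble(site_id = id, metric = metric,
                                  condition = conditions,
                                  value = unname(sm$values)),
         perm = if (!is.null(pt)) dplyr::mutate(tidy(pt), site_id = id,
                                                .before = 1),
         excluded = empty$excluded)
  }

  res <- analyze_site(rt_a)
  if (design == "ot10_imc_paired") {
    res_b <- analyze_site(build_rate_table(entries$site_b,
                                           window_policy = window_policy))
    res <- list(metrics = dplyr::bind_rows(res$metrics, res_b$metrics),
                perm = dplyr::bind_rows(res$perm, res_b$perm),
                excluded = dplyr::bind_rows(res$excluded, res_b$excluded))
  }
  res
}

population_summary <- function(wide, metric, conditions) {
  out <- list(metric = metric, n_sites = nrow(wide))
  if (!all(c("baseline", "drug") %in% conditions) ||
      all(is.na(wide$difference))) {
    return(out)
  }
  d <- wide$difference
  n_before <- length(d)
  if (n_before >= 4) {
    scr <- remove_outliers(d)
    kept_idx <- setdiff(seq_along(d), scr$removed_indices)
    out$outlier_indices <- scr$removed_indices
  } else {
    kept_idx <- seq_along(d)
    out$outlier_indices <- integer(0)
  }
  kept <- wide[kept_idx, , drop = FALSE]
  out$n_before <- n_before
  out$n_removed <- n_before - nrow(kept)
  out$n_after <- nrow(kept)
  out$median_difference <- stats::median(kept$difference)
  if (nrow(kept) >= 5) {
    out$test_name <- "two-sided sign-rank (drug vs baseline)"
    out$p_value <- paired_signrank(kept$value_drug, kept$value_baseline)
  }
  out
}

#' Pairwise recovery comparisons with Holm correction
#'
#' For metrics measured in all three conditions, runs the three paired
#' two-sided sign-rank tests (baseline vs drug, drug vs recovery, baseline vs
#' recovery) and Holm-adjusts the p-values. Sites missing any condition are
#' dropped with a message.
#'
#' @param site_summary A wide per-site tibble with columns `value_baseline`,
#'   `value_drug`, `value_recovery` (as in an `experiment_result`).
#' @param metric Metric label carried into the output.
#' @return A tibble with one row per comparison: `metric`, `comparison`,
#'   `n_sites`, `p_raw`, `p_holm`.
#' @export
recovery_report <- function(site_summary, metric = "metric") {
  need <- paste0("value_", conditions_order)
  miss <- setdiff(need, names(site_summary))
  if (length(miss)) {
    stop("need all three conditions; missing: ",
         paste(sub("value_", "", miss), collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(site_summary[, need])
  if (any(!complete)) {
    message(sum(!complete), " site(s) excluded from the recovery report ",
            "(missing a condition)")
  }
  s <- site_summary[complete, , drop = FALSE]
  cmp <- list(
    c("baseline", "drug"),
    c("drug", "recovery"),
    c("baseline", "recovery"))
  p_raw <- vapply(cmp, function(pr) {
    paired_signrank(s[[paste0("value_", pr[1])]],
                    s[[paste0("value_", pr[2])]])
  }, numeric(1))
  tibble::tibble(
    metric = metric,
    comparison = vapply(cmp, paste, character(1), collapse = " vs "),
    n_sites = nrow(s),
    p_raw = p_raw,
    p_holm = holm_correct(p_raw))
}

#' Simulate and analyse an experiment end to end
#'
#' Convenience wrapper: [simulate_experiment()] followed by
#' [analyze_experiment()], with the ground truth attached to the result.
#'
#' @inheritParams simulate_experiment
#' @inheritParams analyze_experiment
#' @param metric Optional; if supplied it must match [metric_for_design()]
#'   (requesting, e.g., the suppression index on a competition design is a
#'   validation error).
#' @return An `experiment_result` with an extra `ground_truth` element.
#' @export
run_experiment <- function(design, n_sites, seed = 1L, base_config = NULL,
                           conditions = c("baseline", "drug"),
                           n_perm = 500, metric = NULL,
                           window_policy = default_window_policy()) {
  design <- match.arg(design, experiment_designs())
  if (!is.null(metric) && metric != metric_for_design(design)) {
    stop("design ", design, " produces metric '", metric_for_design(design),
         "', not '", metric, "'", call. = FALSE)
  }
  sim <- simulate_experiment(design, n_sites, seed = seed,
                             base_config = base_config,
                             conditions = conditions)
  res <- analyze_experiment(sim, n_perm = n_perm, seed = seed,
                            window_policy = window_policy)
  res$ground_truth <- sim$ground_truth
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$design, "| metric:", x$metric, "\n")
  cat(sprintf("  %d site(s) analysed, %d excluded\n",
              dplyr::n_distinct(x$site_metrics$site_id),
              nrow(x$excluded)))
  ps <- x$population_summary
  if (!is.null(ps$median_difference)) {
    cat(sprintf("  median %s difference (drug - baseline): %.4g (n = %d after removing %d outlier(s))\n",
                x$metric, ps$median_difference, ps$n_after, ps$n_removed))
  }
  if (!is.null(ps$p_value)) {
    cat(sprintf("  %s: p = %.4g\n", ps$test_name, ps$p_value))
  }
  if (!is.null(x$recovery)) {
    cat("  recovery comparisons (Holm-corrected):\n")
    print(x$recovery)
  }
  invisible(x)
}

#' @method tidy experiment_result
#' @export
tidy.experiment_result <- function(x, ...) x$site_summary

#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  ps <- x$population_summary
  tibble::tibble(design = x$design, metric = x$metric,
                 n_sites = ps$n_sites %||% NA_integer_,
                 n_removed = ps$n_removed %||% NA_integer_,
                 median_difference = ps$median_difference %||% NA_real_,
                 p_value = ps$p_value %||% NA_real_)
}
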