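#' Read a trial-structured spiking session from disk
#'
#' Sessions are stored as plain tabular files: `trials.csv` (one row per
#' stimulus presentation), `spikes.csv` (`trial_id`, `spike_time_ms`; one row
#' per spike) and `sites.csv` (per-site metadata). Spike times are in ms with
#' 0 at stimulus onset; negative times are the pre-onset segment. The three
#' tables are validated and joined into a single trial tibble with a
#' `spike_times_ms` list-column, the in-memory session format used throughout
#' the package.
#'
#' @param trials_path Path to the trials table.
#' @param spikes_path Path to the spikes table.
#' @param sites_path Path to the site-metadata table.
#' @return A session tibble (one row per trial, sites metadata joined in).
#' @export
read_session <- function(trials_path, spikes_path, sites_path) {
  trials <- readr::read_csv(trials_path, show_col_types = FALSE)
  spikes <- readr::read_csv(spikes_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              trial_id = readr::col_character(),
                              spike_time_ms = readr::col_double()))
  sites <- readr::read_csv(sites_path, show_col_types = FALSE)
  validate_session_tables(trials, spikes, sites)

  spike_lists <- split(spikes$spike_time_ms, spikes$trial_id)
  unsorted <- names(spike_lists)[vapply(spike_lists, is.unsorted, logical(1))]
  if (length(unsorted)) {
    stop("spike times not sorted ascending within trial ", unsorted[1],
         call. = FALSE)
  }
  trials$spike_times_ms <- purrr::map(trials$trial_id, function(id) {
    st <- spike_lists[[id]]
    if (is.null(st)) numeric(0) else st
  })
  tibble::as_tibble(dplyr::left_join(trials, sites, by = "site_id"))
}

required_trial_cols <- c(
  "site_id", "trial_id", "condition", "protocol",
  "s1_azimuth_deg", "s1_elevation_deg", "s1_loom_speed_dps",
  "s2_azimuth_deg", "s2_elevation_deg", "s2_loom_speed_dps",
  "bar_length_deg", "bar_height_deg", "duration_ms")

required_site_cols <- c("site_id", "region", "rf_center_az_deg",
                        "rf_center_el_deg", "contralateral_positive")

validate_session_tables <- function(trials, spikes, sites) {
  miss <- setdiff(required_trial_cols, names(trials))
  if (length(miss)) {
    stop("trials table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(c("trial_id", "spike_time_ms"), names(spikes))
  if (length(miss)) {
    stop("spikes table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(required_site_cols, names(sites))
  if (length(miss)) {
    stop("sites table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(trials$trial_id)) {
    stop("duplicate trial_id in trials table", call. = FALSE)
  }
  bad <- which(!trials$condition %in% c("baseline", "drug", "recovery"))
  if (length(bad)) {
    stop("invalid condition at trials row ", bad[1], ": ",
         trials$condition[bad[1]], call. = FALSE)
  }
  bad <- which(!trials$protocol %in% c("loom_single", "loom_pair", "bar"))
  if (length(bad)) {
    stop("invalid protocol at trials row ", bad[1], call. = FALSE)
  }
  if (!is.numeric(spikes$spike_time_ms) && nrow(spikes) > 0) {
    stop("spike_time_ms must be numeric", call. = FALSE)
  }
  if (anyNA(spikes$spike_time_ms)) {
    stop("non-numeric or missing spike_time_ms at spikes row ",
         which(is.na(spikes$spike_time_ms))[1], call. = FALSE)
  }
  pair <- trials$protocol == "loom_pair"
  bad <- which(pair & (is.na(trials$s2_azimuth_deg) |
                         is.na(trials$s2_loom_speed_dps)))
  if (length(bad)) {
    stop("loom_pair trial missing S2 fields at trials row ", bad[1],
         call. = FALSE)
  }
  bar <- trials$protocol == "bar"
  bad <- which(bar & is.na(trials$bar_length_deg))
  if (length(bad)) {
    stop("bar trial missing bar_length_deg at trials row ", bad[1],
         call. = FALSE)
  }
  orphan <- setdiff(spikes$trial_id, trials$trial_id)
  if (length(orphan)) {
    stop("spikes reference unknown trial_id: ", orphan[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a session to disk
#'
#' Inverse of [read_session()]: splits a session tibble into `trials.csv`,
#' `spikes.csv` and `sites.csv` under `out_dir`. A write -> read round trip
#' reproduces the session content.
#'
#' @param session A session tibble (as from [simulate_session()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_session <- function(session, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial_cols <- intersect(c(required_trial_cols, "repetition"), names(session))
  trials <- session[, trial_cols]
  sites <- dplyr::distinct(session[, intersect(required_site_cols,
                                               names(session))])
  spikes <- tidyr::unnest(
    tibble::tibble(trial_id = session$trial_id,
                   spike_time_ms = session$spike_times_ms),
    "spike_time_ms")
  paths <- c(trials = file.path(out_dir, "trials.csv"),
             spikes = file.path(out_dir, "spikes.csv"),
             sites = file.path(out_dir, "sites.csv"))
  readr::write_csv(trials, paths[["trials"]])
  readr::write_csv(spikes, paths[["spikes"]])
  readr::write_csv(sites, paths[["sites"]])
  invisible(paths)
}

#' Write analysis result tables
#'
#' Writes the per-site metrics table (`site_metrics.csv`, deterministic column
#' order), the per-site permutation results (`perm_results.json`) and the
#' population summary (`population_summary.json`).
#'
#' @param site_metrics Tibble of per-site metric rows.
#' @param population_summary Named list (or NULL) of population-level results.
#' @param out_dir Output directory.
#' @param perm_results Optional tibble of permutation-test results.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_results <- function(site_metrics, population_summary, out_dir,
                          perm_results = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lead <- intersect(c("site_id", "condition", "metric", "value", "si", "slope",
                      "intercept", "n_points", "flag"), names(site_metrics))
  site_metrics <- site_metrics[, c(lead, setdiff(names(site_metrics), lead))]
  paths <- c(site_metrics = file.path(out_dir, "site_metrics.csv"))
  readr::write_csv(site_metrics, paths[["site_metrics"]])
  if (!is.null(population_summary)) {
    paths[["population_summary"]] <- file.path(out_dir,
                                               "population_summary.json")
    jsonlite::write_json(population_summary, paths[["population_summary"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  if (!is.null(perm_results)) {
    paths[["perm_results"]] <- file.path(out_dir, "perm_results.json")
    jsonlite::write_json(perm_results, paths[["perm_results"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
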