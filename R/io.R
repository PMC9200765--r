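# Delimited-text readers/writers for trial tables and spike trains, YAML
# run configuration, and the JSON analysis report. Angles are stored in
# degrees; spike times in seconds relative to the predicted collision.

trial_required_cols <- c(
  "crab_id", "sex", "treatment", "stim_azimuth_1", "stim_azimuth_2",
  "contrast_1", "contrast_2", "body_orientation_deg", "responded",
  "time_to_collision_s", "escape_direction_deg"
)

#' Read / write escape-trial tables
#'
#' CSV with one row per trial. Required columns: `crab_id`, `sex`,
#' `treatment`, `stim_azimuth_1`, `stim_azimuth_2`, `contrast_1`,
#' `contrast_2`, `body_orientation_deg`, `responded`,
#' `time_to_collision_s`, `escape_direction_deg`. Non-responding trials may
#' leave timing and direction empty; responding trials must not. Angles are
#' normalised to `[0, 360)` on read; angles outside `[0, 360]` raise a row
#' error with the offending line.
#'
#' @param path File path.
#' @return `read_trials()`: a validated tibble.
#' @export
read_trials <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trial_required_cols, names(tab))
  if (length(missing) > 0L) {
    abort(sprintf("Trial table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "loomattend_schema_error")
  }
  tab$responded <- as.logical(tab$responded)
  for (col in c("body_orientation_deg", "escape_direction_deg",
                "stim_azimuth_1", "stim_azimuth_2")) {
    bad <- which(!is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 360))
    if (length(bad) > 0L) {
      abort(sprintf("Column %s out of [0, 360] at data row(s) %s.",
                    col, paste(head(bad, 5L), collapse = ", ")),
            class = "loomattend_row_error")
    }
    tab[[col]] <- ifelse(is.na(tab[[col]]), NA_real_, norm_angle(tab[[col]]))
  }
  bad <- which(tab$responded & is.na(tab$escape_direction_deg))
  if (length(bad) > 0L) {
    abort(sprintf("Responding trial(s) without escape direction at row(s) %s.",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "loomattend_row_error")
  }
  tab
}

#' @rdname read_trials
#' @param trials Tibble of trials (as from [gen_escape_trials()]).
#' @return `write_trials()`: `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_required_cols, names(trials))
  if (length(missing) > 0L) {
    abort(sprintf("Trial table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "loomattend_schema_error")
  }
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Read / write spike trains
#'
#' Long-format event CSV (`neuron_id`, `crab_id`, `trial_id`, `treatment`,
#' `spike_time_s`, one row per spike) plus a companion trial metadata CSV
#' (`trial_id`, `neuron_id`, `crab_id`, `treatment`, `trial_start`,
#' `trial_end`, `spont_start`, `spont_end`). Times are sorted on read;
#' spikes outside the declared spans raise a row error naming the trial.
#'
#' @param spikes_path,meta_path Paths of the event and metadata files.
#' @return `read_spikes()`: a tibble with one row per trial and list-column
#'   `spike_times`.
#' @export
read_spikes <- function(spikes_path, meta_path) {
  ev <- readr::read_csv(spikes_path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  need_ev <- c("neuron_id", "crab_id", "trial_id", "treatment", "spike_time_s")
  need_meta <- c("trial_id", "neuron_id", "crab_id", "treatment",
                 "trial_start", "trial_end", "spont_start", "spont_end")
  for (nm in list(list(ev, need_ev, "event"), list(meta, need_meta, "metadata"))) {
    missing <- setdiff(nm[[2]], names(nm[[1]]))
    if (length(missing) > 0L) {
      abort(sprintf("Spike %s table is missing column(s): %s",
                    nm[[3]], paste(missing, collapse = ", ")),
            class = "loomattend_schema_error")
    }
  }
  out <- meta
  out$spike_times <- purrr::map(meta$trial_id, function(id) {
    sort(ev$spike_time_s[ev$trial_id == id])
  })
  for (i in seq_len(nrow(out))) {
    st <- out$spike_times[[i]]
    lo <- min(out$spont_start[i], out$trial_start[i])
    hi <- max(out$spont_end[i], out$trial_end[i])
    if (length(st) > 0L && (min(st) < lo || max(st) > hi)) {
      abort(sprintf("Spike outside declared span in trial %s.",
                    out$trial_id[i]),
            class = "loomattend_row_error")
    }
  }
  out$n_spikes <- lengths(out$spike_times)
  out
}

#' @rdname read_spikes
#' @param trains Tibble of spike trains (as from [gen_spike_population()]);
#'   a `trial_id` column is added if absent.
#' @return `write_spikes()`: invisibly, a list with the two paths written.
#' @export
write_spikes <- function(trains, spikes_path, meta_path) {
  if (!"trial_id" %in% names(trains)) {
    trains$trial_id <- sprintf("trial%04d", seq_len(nrow(trains)))
  }
  ev <- trains %>%
    dplyr::select("neuron_id", "crab_id", "trial_id", "treatment",
                  "spike_times") %>%
    tidyr::unnest_longer("spike_times", values_to = "spike_time_s")
  meta <- trains %>%
    dplyr::select("trial_id", "neuron_id", "crab_id", "treatment",
                  "trial_start", "trial_end", "spont_start", "spont_end")
  readr::write_csv(ev, spikes_path, progress = FALSE)
  readr::write_csv(meta, meta_path, progress = FALSE)
  invisible(list(spikes = spikes_path, meta = meta_path))
}

#' Run configuration
#'
#' A run configuration bundles the seed, the treatment set, generator
#' parameters and analysis thresholds for a full synthetic study, and is
#' serialised as YAML (text-diffable).
#'
#' @param seed Integer seed; mandatory, every stochastic step derives from
#'   it.
#' @param experiment Canonical treatment set to use (1 or 2).
#' @param n_crabs Behavioural sample size.
#' @param n_neurons Neurons per neuron type.
#' @param behavior A [behavior_params()] object.
#' @param spikes A [spike_params()] object.
#' @param alpha,n_perm,n_boot,fwhm,dt,min_duration Analysis thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, experiment = 1, n_crabs = 50, n_neurons = 17,
                       behavior = behavior_params(), spikes = spike_params(),
                       alpha = 0.05, n_perm = 5000, n_boot = 2000,
                       fwhm = 0.2, dt = 0.005, min_duration = fwhm) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("`seed` is mandatory.", class = "loomattend_invalid_parameter")
  }
  structure(list(
    seed = as.integer(seed), experiment = experiment, n_crabs = n_crabs,
    n_neurons = n_neurons, behavior = unclass(behavior),
    spikes = unclass(spikes), alpha = alpha, n_perm = n_perm,
    n_boot = n_boot, fwhm = fwhm, dt = dt, min_duration = min_duration
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    seed = raw$seed, experiment = raw$experiment %||% 1,
    n_crabs = raw$n_crabs %||% 50, n_neurons = raw$n_neurons %||% 17,
    behavior = do.call(behavior_params, raw$behavior %||% list()),
    spikes = do.call(spike_params, raw$spikes %||% list()),
    alpha = raw$alpha %||% 0.05, n_perm = raw$n_perm %||% 5000,
    n_boot = raw$n_boot %||% 2000, fwhm = raw$fwhm %||% 0.2,
    dt = raw$dt %||% 0.005, min_duration = raw$min_duration %||% 0.2
  )
  cfg
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write / read the analysis report
#'
#' The report is JSON with a provenance block (package version, seed and a
#' hash of the configuration) plus the behavioural and neural results; it
#' round-trips losslessly and is byte-identical for identical config and
#' seed.
#'
#' @param report A named list (see [run_attention_pipeline()]).
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
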