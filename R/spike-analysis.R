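# Spike-train response quantification: Gaussian-kernel instantaneous rate
# with spike-count conservation, spontaneous baseline, 2-SD onset detection,
# and peak/average response metrics.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Internal: trapezoidal integral on a uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Estimate the instantaneous firing rate of a spike train
#'
#' Convolves the spike train with a Gaussian kernel (full width at half
#' maximum `fwhm`, so `sigma = fwhm / (2 sqrt(2 ln 2))`) and rescales the
#' resulting waveform so that its integral over the whole span equals the
#' number of spikes: the estimate conserves spike count exactly. Kernels are
#' truncated at the span edges; the normalisation is applied after
#' truncation so conservation still holds.
#'
#' @param spike_times Sorted spike times (s).
#' @param span Length-2 numeric, the recording span to evaluate over.
#' @param fwhm Kernel full width at half maximum (s), default 0.2.
#' @param dt Grid step (s); must satisfy `dt <= fwhm / 10`. Default 1 ms.
#' @return A tibble of class `rate_profile` with columns `time` and `rate`
#'   (Hz) and attributes `fwhm`, `dt`, `n_spikes`, `span`. An empty train
#'   yields an all-zero profile.
#' @export
#' @examples
#' p <- estimate_rate(0, span = c(-2, 2))
#' max(p$rate)  # ~ 1 / (sigma * sqrt(2 * pi)) ~ 4.698 Hz
estimate_rate <- function(spike_times, span, fwhm = 0.2, dt = 0.001) {
  if (dt > fwhm / 10 + 1e-12) {
    abort("`dt` must be <= fwhm / 10.", class = "loomattend_invalid_parameter")
  }
  if (length(span) != 2L || span[2] <= span[1]) {
    abort("`span` must be an increasing length-2 interval.",
          class = "loomattend_invalid_parameter")
  }
  spike_times <- sort(spike_times)
  grid <- seq(span[1], span[2], by = dt)
  ng <- length(grid)
  n <- length(spike_times)
  rate <- numeric(ng)
  if (n > 0) {
    sigma <- fwhm_to_sigma(fwhm)
    # each kernel only contributes within +-6 sigma of its spike
    halfw <- ceiling(6 * sigma / dt)
    for (t_s in spike_times) {
      j0 <- round((t_s - span[1]) / dt) + 1
      jj <- max(1L, j0 - halfw):min(ng, j0 + halfw)
      rate[jj] <- rate[jj] + dnorm(grid[jj] - t_s, sd = sigma)
    }
    integral <- trapz(grid, rate)
    if (integral > 0) rate <- rate * n / integral
  }
  structure(
    tibble::tibble(time = grid, rate = rate),
    fwhm = fwhm, dt = dt, n_spikes = n, span = span,
    class = c("rate_profile", class(tibble::tibble()))
  )
}

#' Spontaneous-activity statistics of a rate profile
#'
#' Mean and SD of the instantaneous rate over the unstimulated span, with
#' `3 * sigma` trimmed from each edge so kernel truncation does not bias
#' the baseline.
#'
#' @param profile A [estimate_rate()] profile covering the spontaneous span.
#' @param spont_span Length-2 numeric, the unstimulated interval (s); must
#'   be at least `10 * fwhm` long.
#' @return One-row tibble: `mean_rate`, `sd_rate` (Hz). An empty segment
#'   gives `(0, 0)`.
#' @export
spontaneous_stats <- function(profile, spont_span) {
  fwhm <- attr(profile, "fwhm")
  if (diff(spont_span) < 10 * fwhm) {
    abort("Spontaneous span must be >= 10 * fwhm.",
          class = "loomattend_invalid_input")
  }
  trim <- 3 * fwhm_to_sigma(fwhm)
  keep <- profile$time >= spont_span[1] + trim &
    profile$time <= spont_span[2] - trim
  r <- profile$rate[keep]
  if (length(r) == 0L || all(r == 0)) {
    return(tibble::tibble(mean_rate = 0, sd_rate = 0))
  }
  tibble::tibble(mean_rate = mean(r), sd_rate = sd(r))
}

#' Detect response onset from a rate profile
#'
#' Earliest time at which the instantaneous rate exceeds
#' `spont_mean + 2 * spont_sd` and stays above that threshold for at least
#' `min_duration` (default one kernel FWHM, which suppresses single-sample
#' crossings).
#'
#' @param profile A `rate_profile`.
#' @param spont_mean,spont_sd Spontaneous baseline statistics (Hz).
#' @param min_duration Minimum supra-threshold duration (s); defaults to the
#'   profile's kernel FWHM.
#' @param window Optional length-2 interval restricting the search (e.g. the
#'   stimulated span); default is the whole profile.
#' @param anchor_peak If `TRUE`, return the start of the qualifying
#'   supra-threshold run that contains the rate maximum of the window
#'   rather than the earliest qualifying run. A looming-driven response
#'   rises through threshold and stays up through its peak, so anchoring on
#'   the peak makes the onset robust to brief baseline excursions earlier
#'   in the trial; the earliest-run convention remains the default.
#' @return Onset time (s, profile time base) or `NA_real_` if the threshold
#'   is never exceeded long enough.
#' @export
detect_onset <- function(profile, spont_mean, spont_sd,
                         min_duration = attr(profile, "fwhm"),
                         window = NULL, anchor_peak = FALSE) {
  thr <- spont_mean + 2 * spont_sd
  t <- profile$time
  r <- profile$rate
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; r <- r[keep]
  }
  if (length(t) == 0L) return(NA_real_)
  above <- r > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dt <- attr(profile, "dt")
  ok <- runs$values & (runs$lengths - 1L) * dt >= min_duration
  if (!any(ok)) return(NA_real_)
  if (anchor_peak) {
    i_max <- which.max(r)
    hit <- ok & starts <= i_max & ends >= i_max
    if (any(hit)) return(t[starts[which(hit)[1]]])
  }
  t[starts[which(ok)[1]]]
}

#' Response metrics from a rate profile
#'
#' Peak and average instantaneous rate over the response window (onset to
#' end of stimulation), plus the onset expressed as time to collision
#' (positive values mean before the predicted collision).
#'
#' @param profile A `rate_profile`.
#' @param onset Onset time (s, profile time base) or `NA` for no response.
#' @param stim_end End of stimulation on the profile time base; with times
#'   relative to collision this is 0.
#' @return One-row tibble: `responded`, `onset_time_to_collision`,
#'   `peak_rate`, `mean_rate_during_response`.
#' @export
response_metrics <- function(profile, onset, stim_end = 0) {
  if (is.na(onset)) {
    return(tibble::tibble(responded = FALSE,
                          onset_time_to_collision = NA_real_,
                          peak_rate = NA_real_,
                          mean_rate_during_response = NA_real_))
  }
  keep <- profile$time >= onset & profile$time <= stim_end
  r <- profile$rate[keep]
  if (length(r) == 0L) {
    abort("Response window contains no grid points.",
          class = "loomattend_invalid_input")
  }
  tibble::tibble(
    responded = TRUE,
    onset_time_to_collision = stim_end - onset,
    peak_rate = max(r),
    mean_rate_during_response = mean(r)
  )
}

#' Analyse a table of spike trains
#'
#' Runs the full response-quantification chain for each train of a
#' [gen_spike_population()]-style tibble: kernel rate estimate over the
#' whole recording, spontaneous baseline, onset detection within the
#' stimulated span, and response metrics.
#'
#' @param trains Tibble with list-column `spike_times` and columns
#'   `trial_start`, `trial_end`, `spont_start`, `spont_end` (plus any
#'   metadata, which is carried through).
#' @param fwhm Kernel FWHM (s).
#' @param dt Rate-grid step (s).
#' @param min_duration Minimum supra-threshold duration (s) handed to
#'   [detect_onset()]. The default for population analyses is `2 * fwhm`:
#'   a looming-driven response stays above threshold from onset until the
#'   end of stimulation, so the longer criterion discards brief baseline
#'   excursions (a handful of coincident spikes) without delaying true
#'   onsets by more than the kernel width.
#' @param pool_reps If `TRUE`, repeat presentations of the same
#'   neuron-treatment pair are pooled into a trial-averaged rate profile
#'   (spikes concatenated, rate divided by the number of repeats) before
#'   baseline, onset and metric extraction -- the usual PSTH treatment of
#'   repeated trials. If `FALSE` (default), each train is analysed alone.
#' @param window_per `"train"` (default): peak and average rate are taken
#'   over each train's own response window, onset to end of stimulation.
#'   `"neuron"`: within each neuron the response window starts at the
#'   earliest onset observed across its treatments, so rates of different
#'   treatments are measured over a common interval and compose additively
#'   -- required when single-stimulus responses are used to predict paired
#'   responses (see [neural_decision()]). Reported onsets are unaffected.
#' @return The metadata columns of `trains` joined with `spont_mean`,
#'   `spont_sd` and the [response_metrics()] columns; one row per train, or
#'   per neuron-treatment pair when `pool_reps = TRUE` (with an `n_reps`
#'   column).
#' @export
analyze_spike_trains <- function(trains, fwhm = 0.2, dt = 0.005,
                                 min_duration = 2 * fwhm,
                                 pool_reps = FALSE,
                                 window_per = c("train", "neuron")) {
  window_per <- match.arg(window_per)
  if (pool_reps) {
    trains <- trains %>%
      dplyr::group_by(.data$neuron_id, .data$treatment) %>%
      dplyr::summarise(
        spike_times = list(sort(unlist(.data$spike_times))),
        dplyr::across(dplyr::any_of(c("crab_id", "rule")), dplyr::first),
        trial_start = .data$trial_start[1], trial_end = .data$trial_end[1],
        spont_start = .data$spont_start[1], spont_end = .data$spont_end[1],
        n_reps = dplyr::n(), .groups = "drop"
      )
  }
  meta_cols <- setdiff(names(trains),
                       c("spike_times", "spont_start", "spont_end",
                         "trial_start", "trial_end"))
  pieces <- purrr::map(seq_len(nrow(trains)), function(i) {
    row <- trains[i, ]
    scale <- if (pool_reps) row$n_reps else 1L
    prof <- estimate_rate(row$spike_times[[1]],
                          span = c(row$spont_start, row$trial_end),
                          fwhm = fwhm, dt = dt)
    if (scale > 1L) prof$rate <- prof$rate / scale
    sp <- spontaneous_stats(prof, c(row$spont_start, row$spont_end))
    onset <- detect_onset(prof, sp$mean_rate, sp$sd_rate,
                          min_duration = min_duration,
                          window = c(row$trial_start, row$trial_end),
                          anchor_peak = TRUE)
    list(row = row, prof = prof, sp = sp, onset = onset)
  })
  onsets <- vapply(pieces, function(p) p$onset %||% NA_real_, numeric(1))
  win_start <- onsets
  if (window_per == "neuron") {
    ids <- vapply(pieces, function(p) as.character(p$row$neuron_id),
                  character(1))
    for (id in unique(ids)) {
      sel <- ids == id
      if (any(!is.na(onsets[sel]))) {
        win_start[sel] <- min(onsets[sel], na.rm = TRUE)
      }
    }
  }
  res <- purrr::map(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    met <- response_metrics(p$prof, win_start[i], stim_end = p$row$trial_end)
    met$onset_time_to_collision <- if (is.na(p$onset)) NA_real_ else
      p$row$trial_end - p$onset
    met$responded <- !is.na(p$onset) ||
      (window_per == "neuron" && !is.na(win_start[i]))
    dplyr::bind_cols(
      p$row[meta_cols],
      tibble::tibble(spont_mean = p$sp$mean_rate, spont_sd = p$sp$sd_rate),
      met
    )
  })
  dplyr::bind_rows(res)
}
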