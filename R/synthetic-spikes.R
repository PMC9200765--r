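# Inhomogeneous-Poisson spike generator for looming-sensitive neurons.
# The stimulus-driven rate is proportional to the angular expansion rate of
# the looming disk scaled by |Weber contrast| and a receptive-field weight,
# which makes the firing rate climb steeply towards the predicted collision
# and lets lower contrast delay threshold crossing -- the qualitative
# signature of the recorded cells.

#' Parameters of the spike-train generator
#'
#' @param spont_rate Spontaneous (unstimulated) firing rate, Hz. Looming-
#'   sensitive lobula giants fire sparsely when unstimulated; default 2 Hz.
#' @param gain Driven-rate gain, Hz per deg/s of angular expansion.
#' @param integration_rule How drives from two simultaneous stimuli combine:
#'   `"max"` (select the stronger input), `"sum"`, or `"average"`.
#' @param contrast_scaling Multiplier on `|weber contrast|` in the drive.
#' @param receptive_weight_primary,receptive_weight_secondary Dimensionless
#'   receptive-field weights for the primary and secondary stimulus
#'   locations. Unequal weights emulate the receptive-field inhomogeneity of
#'   MLG1 units; set them equal for the near-uniform MLG2 field.
#' @param trial_span Stimulated span (s) ending at the predicted collision.
#' @param spont_span Span (s) of unstimulated recording preceding the trial.
#' @param dt Grid step (s) for rate evaluation and thinning.
#' @return A list of class `spike_params`.
#' @export
spike_params <- function(spont_rate = 2, gain = 0.5,
                         integration_rule = c("max", "sum", "average"),
                         contrast_scaling = 1,
                         receptive_weight_primary = 1,
                         receptive_weight_secondary = 0.6,
                         trial_span = 11, spont_span = 20, dt = 0.001) {
  integration_rule <- match.arg(integration_rule)
  if (spont_rate < 0 || gain < 0) {
    abort("Rates and gain must be >= 0.",
          class = "loomattend_invalid_parameter")
  }
  if (trial_span <= 0 || spont_span <= 0 || dt <= 0) {
    abort("Spans and dt must be > 0.", class = "loomattend_invalid_parameter")
  }
  structure(list(
    spont_rate = spont_rate, gain = gain,
    integration_rule = integration_rule, contrast_scaling = contrast_scaling,
    receptive_weight_primary = receptive_weight_primary,
    receptive_weight_secondary = receptive_weight_secondary,
    trial_span = trial_span, spont_span = spont_span, dt = dt
  ), class = "spike_params")
}

#' Stimulus-driven firing rate of a model looming-sensitive neuron
#'
#' Evaluates `lambda(t) = spont_rate + gain * combine_i(w_i * |c_i| *
#' contrast_scaling * expansion_rate_i(t))` on a time grid, where `combine`
#' is the configured integration rule. Times are seconds relative to the
#' predicted collision (negative before collision).
#'
#' @param stimuli List of [looming_stimulus()] objects (>= 1).
#' @param params A [spike_params()] object.
#' @param weights Receptive-field weight per stimulus; defaults to
#'   `receptive_weight_primary` for the first stimulus and
#'   `receptive_weight_secondary` for any second one.
#' @param times Times (s, relative to collision) at which to evaluate.
#' @return Numeric vector of rates (Hz), same length as `times`.
#' @export
driven_rate <- function(stimuli, params, weights = NULL,
                        times = seq(-params$trial_span, 0, by = params$dt)) {
  if (length(stimuli) < 1L) {
    abort("Need >= 1 stimulus.", class = "loomattend_invalid_parameter")
  }
  if (is.null(weights)) {
    weights <- c(params$receptive_weight_primary,
                 params$receptive_weight_secondary)[seq_along(stimuli)]
  }
  tau <- pmax(-times, 1e-9)   # time to collision; clamp at collision itself
  drives <- vapply(seq_along(stimuli), function(i) {
    weights[i] * abs(stimuli[[i]]$contrast) * params$contrast_scaling *
      expansion_rate(stimuli[[i]], tau)
  }, numeric(length(tau)))
  drives <- matrix(drives, nrow = length(tau))
  combined <- switch(params$integration_rule,
    max = do.call(pmax, as.data.frame(drives)),
    sum = rowSums(drives),
    average = rowMeans(drives)
  )
  params$spont_rate + params$gain * combined
}

#' Generate a spike train from looming stimuli
#'
#' Inhomogeneous Poisson process by thinning: the driven rate of
#' [driven_rate()] over `[-trial_span, 0]`, preceded by a homogeneous
#' spontaneous segment at `spont_rate` over `[-trial_span - spont_span,
#' -trial_span)`. All times are relative to the predicted collision.
#'
#' @inheritParams driven_rate
#' @param seed Optional integer seed; output is reproducible from it.
#' @return A one-row tibble with list-column `spike_times` (sorted, s) and
#'   columns `trial_start`, `trial_end`, `spont_start`, `spont_end`,
#'   `n_spikes`. A zero-rate configuration yields an empty train.
#' @export
#' @examples
#' tr <- gen_spike_train(list(looming_stimulus(speed_mm_s = 90,
#'                                             start_distance_mm = 1000)),
#'                       spike_params(), seed = 1)
#' tr$n_spikes
gen_spike_train <- function(stimuli, params = spike_params(), weights = NULL,
                            seed = NULL) {
  with_seed(seed, {
    t0 <- -params$trial_span
    grid <- seq(t0, 0, by = params$dt)
    lam <- driven_rate(stimuli, params, weights, grid)
    lam_max <- max(lam)
    trial_spikes <- numeric(0)
    if (lam_max > 0) {
      n_cand <- rpois(1, lam_max * params$trial_span)
      if (n_cand > 0) {
        cand <- sort(runif(n_cand, t0, 0))
        lam_c <- approx(grid, lam, xout = cand, rule = 2)$y
        trial_spikes <- cand[runif(n_cand) < lam_c / lam_max]
      }
    }
    spont_spikes <- numeric(0)
    if (params$spont_rate > 0) {
      n_sp <- rpois(1, params$spont_rate * params$spont_span)
      if (n_sp > 0) {
        spont_spikes <- sort(runif(n_sp, t0 - params$spont_span, t0))
      }
    }
    st <- c(spont_spikes, trial_spikes)
    tibble::tibble(
      spike_times = list(st),
      trial_start = t0, trial_end = 0,
      spont_start = t0 - params$spont_span, spont_end = t0,
      n_spikes = length(st)
    )
  })
}

#' Simulate a population of looming-sensitive neurons
#'
#' For each neuron, draws receptive-field weights for a primary and a
#' secondary stimulus location and generates one spike train per treatment:
#' `Primary` (single stimulus at the primary location), `Secondary` (single
#' at the secondary location) and `Paired` (both, combined under the
#' generator's integration rule). MLG1-like neurons have unequal weights
#' (receptive-field inhomogeneity); MLG2-like neurons have equal weights.
#'
#' @param n_neurons Number of neurons.
#' @param params A [spike_params()] object; its `integration_rule` is the
#'   ground truth the population is generated under.
#' @param neuron_type `"MLG1"` (unequal receptive weights, jittered per
#'   neuron) or `"MLG2"` (uniform field).
#' @param contrasts Length-2 Weber contrasts for the primary and secondary
#'   stimulus (default both -100%).
#' @param stimulus Geometry shared by all stimuli; default is the
#'   electrophysiology stimulus (30 mm disk, 90 mm/s from 1000 mm).
#' @param weight_jitter SD of the per-neuron multiplicative jitter on the
#'   receptive weights.
#' @param n_reps Repeat presentations of each treatment per neuron
#'   (default 6, within the usual range for looming-neuron protocols).
#' @param seed Optional integer seed.
#' @return A tibble of spike trains with columns `neuron_id`, `crab_id`,
#'   `treatment`, `rule`, plus the train columns of [gen_spike_train()].
#' @export
gen_spike_population <- function(n_neurons, params = spike_params(),
                                 neuron_type = c("MLG1", "MLG2"),
                                 contrasts = c(-1, -1),
                                 stimulus = looming_stimulus(
                                   speed_mm_s = 90, start_distance_mm = 1000),
                                 weight_jitter = 0.1, n_reps = 6,
                                 seed = NULL) {
  neuron_type <- match.arg(neuron_type)
  with_seed(seed, {
    rows <- vector("list", n_neurons * 3L * n_reps)
    k <- 0L
    for (i in seq_len(n_neurons)) {
      base_w <- if (neuron_type == "MLG1") {
        c(params$receptive_weight_primary, params$receptive_weight_secondary)
      } else {
        rep(params$receptive_weight_primary, 2L)
      }
      w <- base_w * exp(rnorm(2, 0, weight_jitter))
      if (neuron_type == "MLG1") w <- sort(w, decreasing = TRUE)
      s_prim <- looming_stimulus(
        diameter_mm = stimulus$diameter_mm, speed_mm_s = stimulus$speed_mm_s,
        start_distance_mm = stimulus$start_distance_mm,
        contrast = contrasts[1], azimuth_deg = 0)
      s_sec <- looming_stimulus(
        diameter_mm = stimulus$diameter_mm, speed_mm_s = stimulus$speed_mm_s,
        start_distance_mm = stimulus$start_distance_mm,
        contrast = contrasts[2], azimuth_deg = 270)
      cfg <- list(
        Primary = list(stimuli = list(s_prim), weights = w[1]),
        Secondary = list(stimuli = list(s_sec), weights = w[2]),
        Paired = list(stimuli = list(s_prim, s_sec), weights = w)
      )
      for (tr_name in names(cfg)) {
        for (rep_i in seq_len(n_reps)) {
          k <- k + 1L
          tr <- gen_spike_train(cfg[[tr_name]]$stimuli, params,
                                weights = cfg[[tr_name]]$weights)
          tr$neuron_id <- sprintf("%s_%02d", neuron_type, i)
          tr$crab_id <- sprintf("crab%03d", (i + 1L) %/% 2L)
          tr$treatment <- tr_name
          tr$rep <- rep_i
          tr$rule <- params$integration_rule
          rows[[k]] <- tr
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
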