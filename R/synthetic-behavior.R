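# Seeded generator for synthetic escape-trial tables. The generator encodes
# the statistical structure the downstream analysis assumes: escape
# directions are von Mises mixtures whose modes follow the selective or
# divided-attention predictions, stimulus choice is biased by body-axis
# alignment and by contrast, and response timing lives on the square-root
# time-to-collision scale with a per-crab random intercept.

#' Treatment specifications for single and paired looming stimuli
#'
#' @param name Treatment name. The canonical set is `Single`, `Paired90`,
#'   `Paired180` (equal contrast) and `SingleLC`, `SingleHC`,
#'   `PairedContrast90`, `PairedContrast180` (mixed contrast).
#' @param azimuths One or two stimulus approach azimuths (deg). Paired-90
#'   treatments must be separated by exactly 90 deg, paired-180 by 180 deg.
#' @param contrasts Weber contrasts, one per stimulus, each in `[-1, 0]`.
#' @return A one-row tibble with list-columns `azimuths` and `contrasts`.
#' @export
#' @examples
#' treatment_spec("Paired90", c(0, 270), c(-1, -1))
treatment_spec <- function(name, azimuths, contrasts) {
  if (!length(azimuths) %in% 1:2) {
    abort("A treatment has one or two stimuli.",
          class = "loomattend_invalid_parameter")
  }
  if (length(contrasts) != length(azimuths)) {
    abort("One contrast per stimulus azimuth.",
          class = "loomattend_invalid_parameter")
  }
  if (any(contrasts < -1 | contrasts > 0)) {
    abort("Contrasts must lie in [-1, 0].",
          class = "loomattend_invalid_parameter")
  }
  if (length(azimuths) == 2L) {
    sep <- abs(ang_diff(azimuths[2], azimuths[1]))
    if (grepl("90$", name) && !isTRUE(all.equal(sep, 90))) {
      abort("A *90 treatment needs exactly 90 deg separation.",
            class = "loomattend_invalid_parameter")
    }
    if (grepl("180$", name) && !isTRUE(all.equal(sep, 180))) {
      abort("A *180 treatment needs exactly 180 deg separation.",
            class = "loomattend_invalid_parameter")
    }
  }
  tibble::tibble(treatment = name,
                 azimuths = list(norm_angle(azimuths)),
                 contrasts = list(contrasts))
}

#' Canonical treatment sets
#'
#' Experiment 1 uses three equal-contrast treatments (Single, Paired90,
#' Paired180, all -100% Weber contrast); experiment 2 varies contrast
#' (single low -40%, single high -100%, and mixed-contrast pairs). All
#' angles are in the stimulus frame: the (first) stimulus approaches from
#' 0 deg, the second from 270 deg (paired 90) or 180 deg (paired 180).
#'
#' @param experiment 1 (equal contrast) or 2 (contrast manipulation).
#' @return A tibble of treatment specs.
#' @export
default_treatments <- function(experiment = 1) {
  if (experiment == 1) {
    dplyr::bind_rows(
      treatment_spec("Single", 0, -1),
      treatment_spec("Paired90", c(0, 270), c(-1, -1)),
      treatment_spec("Paired180", c(0, 180), c(-1, -1))
    )
  } else if (experiment == 2) {
    dplyr::bind_rows(
      treatment_spec("SingleLC", 0, -0.4),
      treatment_spec("SingleHC", 0, -1),
      treatment_spec("PairedContrast90", c(0, 270), c(-1, -0.4)),
      treatment_spec("PairedContrast180", c(0, 180), c(-1, -0.4))
    )
  } else {
    abort("`experiment` must be 1 or 2.",
          class = "loomattend_invalid_parameter")
  }
}

#' Parameters of the behavioural generator
#'
#' @param response_prob Probability that a trial ends in an escape run;
#'   scalar or named vector by treatment. Default 0.754, the overall response
#'   probability observed on the treadmill.
#' @param kappa von Mises concentration of escape directions around the
#'   chosen mode (> 0).
#' @param attention_mode `"selective"` (respond to exactly one stimulus),
#'   `"divided"` (run at the direction maximising distance from both), or
#'   `"mixed"`.
#' @param divided_fraction Probability of a divided-attention trial when
#'   `attention_mode = "mixed"`.
#' @param lateral_bias_strength Soft-max weight on `|sin(azimuth - body
#'   long axis)|` when choosing which stimulus to flee: 0 = no bias, larger
#'   values favour the stimulus nearer the animal's lateral axis.
#' @param contrast_bias_strength Soft-max weight on `|contrast|` in the same
#'   choice: larger values favour the higher-contrast stimulus.
#' @param timing_mean_sqrt,timing_sd_sqrt Mean and SD of response time to
#'   collision on the square-root-seconds scale.
#' @param timing_contrast_slope Shift of the sqrt-scale timing mean per unit
#'   `|contrast|` below 1 (so a -40% stimulus responds
#'   `0.6 * timing_contrast_slope` sqrt-s later than a -100% one).
#' @param crab_sd Between-crab SD of the sqrt-scale timing intercept.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(response_prob = 0.754, kappa = 8,
                            attention_mode = c("selective", "divided", "mixed"),
                            divided_fraction = 0.5,
                            lateral_bias_strength = 2,
                            contrast_bias_strength = 3,
                            timing_mean_sqrt = 1.6, timing_sd_sqrt = 0.25,
                            timing_contrast_slope = 0.5, crab_sd = 0.15) {
  attention_mode <- match.arg(attention_mode)
  if (any(response_prob < 0 | response_prob > 1) ||
      divided_fraction < 0 || divided_fraction > 1) {
    abort("Probabilities must lie in [0, 1].",
          class = "loomattend_invalid_parameter")
  }
  if (kappa <= 0) {
    abort("`kappa` must be > 0.", class = "loomattend_invalid_parameter")
  }
  if (timing_sd_sqrt < 0 || crab_sd < 0 || lateral_bias_strength < 0 ||
      contrast_bias_strength < 0) {
    abort("SDs and bias strengths must be >= 0.",
          class = "loomattend_invalid_parameter")
  }
  structure(list(
    response_prob = response_prob, kappa = kappa,
    attention_mode = attention_mode, divided_fraction = divided_fraction,
    lateral_bias_strength = lateral_bias_strength,
    contrast_bias_strength = contrast_bias_strength,
    timing_mean_sqrt = timing_mean_sqrt, timing_sd_sqrt = timing_sd_sqrt,
    timing_contrast_slope = timing_contrast_slope, crab_sd = crab_sd
  ), class = "behavior_params")
}

#' Latin-square treatment ordering
#'
#' Randomised Latin square: each subject receives every treatment exactly
#' once and each treatment occupies each serial position equally often. When
#' there are more subjects than treatments the square's rows are recycled.
#'
#' @param n_treatments Number of treatments (>= 2).
#' @param n_subjects Number of subjects (rows; rows cycle if larger than
#'   `n_treatments`).
#' @param seed Optional integer seed.
#' @return Integer matrix `n_subjects x n_treatments`; entry `[s, j]` is the
#'   treatment shown to subject `s` at serial position `j`.
#' @export
#' @examples
#' gen_latin_square(3, 3, seed = 1)
gen_latin_square <- function(n_treatments, n_subjects = n_treatments,
                             seed = NULL) {
  if (n_treatments < 2L) {
    abort("Need >= 2 treatments.", class = "loomattend_invalid_parameter")
  }
  with_seed(seed, {
    n <- n_treatments
    base <- outer(seq_len(n) - 1L, seq_len(n) - 1L, `+`) %% n + 1L
    sym <- sample.int(n)           # relabel treatments
    sq <- matrix(sym[base], n, n)
    sq <- sq[sample.int(n), , drop = FALSE]  # permute rows (subjects)
    rows <- rep(seq_len(n), length.out = n_subjects)
    sq[rows, , drop = FALSE]
  })
}

# Internal: predicted modes given azimuths and hypothesis (degrees).
away_modes <- function(azimuths, hypothesis) {
  away <- norm_angle(azimuths + 180)
  if (hypothesis == "selective" || length(azimuths) == 1L) return(away)
  m <- circ_moments(away)
  if (m$rho < 1e-9) {
    # antipodal stimuli: two orthogonal solutions
    norm_angle(azimuths[1] + c(90, 270))
  } else {
    m$mean_deg
  }
}

#' Generate a synthetic escape-trial table
#'
#' Simulates tethered-treadmill escape trials. Per trial: body orientation is
#' uniform on the circle; the animal responds with the treatment's response
#' probability; on responding trials, under selective attention one stimulus
#' is chosen with probability proportional to
#' `exp(b_lat * |sin(azimuth - body axis)|) * exp(b_con * |contrast|)` and
#' the escape direction is von Mises around directly away from it, while
#' under divided attention the direction is von Mises around the circular
#' mean of the away-directions (for antipodal stimuli one of the two
#' orthogonal solutions is picked at random). Response timing is drawn on
#' the sqrt time-to-collision scale with a per-crab random intercept and
#' squared back. Non-responding trials carry `NA` timing and direction.
#'
#' @param treatments Tibble of [treatment_spec()] rows.
#' @param n_crabs Number of crabs (>= 1).
#' @param trials_per_crab Trials per crab; treatment order follows repeated
#'   Latin squares. Default: one pass over all treatments.
#' @param params A [behavior_params()] object.
#' @param seed Optional integer seed; identical seed and parameters give a
#'   byte-identical table.
#' @return A tibble with one row per trial: `crab_id`, `sex`, `order`,
#'   `treatment`, `stim_azimuth_1`, `stim_azimuth_2`, `contrast_1`,
#'   `contrast_2`, `body_orientation_deg`, `responded`,
#'   `time_to_collision_s`, `escape_direction_deg`, `chosen_stimulus`,
#'   `mode_used`.
#' @export
#' @examples
#' trials <- gen_escape_trials(default_treatments(), n_crabs = 4, seed = 1)
gen_escape_trials <- function(treatments, n_crabs,
                              trials_per_crab = nrow(treatments),
                              params = behavior_params(), seed = NULL) {
  if (nrow(treatments) < 1L) {
    abort("Empty treatment list.", class = "loomattend_invalid_parameter")
  }
  if (n_crabs < 1L) {
    abort("Need >= 1 crab.", class = "loomattend_invalid_parameter")
  }
  n_t <- nrow(treatments)
  with_seed(seed, {
    n_blocks <- ceiling(trials_per_crab / n_t)
    order_mat <- do.call(cbind, lapply(seq_len(n_blocks), function(b) {
      if (n_t == 1L) matrix(1L, n_crabs, 1L) else gen_latin_square(n_t, n_crabs)
    }))[, seq_len(trials_per_crab), drop = FALSE]
    crab_offsets <- rnorm(n_crabs, 0, params$crab_sd)
    sexes <- rep(c("F", "M"), length.out = n_crabs)

    n_rows <- n_crabs * trials_per_crab
    out <- list(
      crab_id = character(n_rows), sex = character(n_rows),
      order = integer(n_rows), treatment = character(n_rows),
      stim_azimuth_1 = numeric(n_rows), stim_azimuth_2 = rep(NA_real_, n_rows),
      contrast_1 = numeric(n_rows), contrast_2 = rep(NA_real_, n_rows),
      body_orientation_deg = numeric(n_rows),
      responded = logical(n_rows),
      time_to_collision_s = rep(NA_real_, n_rows),
      escape_direction_deg = rep(NA_real_, n_rows),
      chosen_stimulus = rep(NA_integer_, n_rows),
      mode_used = rep(NA_character_, n_rows)
    )
    k <- 0L
    for (s in seq_len(n_crabs)) {
      for (j in seq_len(trials_per_crab)) {
        k <- k + 1L
        ti <- order_mat[s, j]
        az <- treatments$azimuths[[ti]]
        con <- treatments$contrasts[[ti]]
        name <- treatments$treatment[ti]
        body <- runif(1, 0, 360)
        p_resp <- if (length(params$response_prob) > 1L) {
          unname(params$response_prob[[name]])
        } else {
          params$response_prob
        }
        responded <- runif(1) < p_resp
        if (responded) {
          mode_used <- switch(params$attention_mode,
            selective = "selective",
            divided = "divided",
            mixed = if (runif(1) < params$divided_fraction) "divided"
                    else "selective")
          if (mode_used == "selective") {
            wl <- params$lateral_bias_strength *
              abs(sin(deg2rad(az - body)))
            wc <- params$contrast_bias_strength * abs(con)
            w <- exp(wl + wc)
            chosen <- sample.int(length(az), 1L, prob = w)
            mu <- norm_angle(az[chosen] + 180)
            c_eff <- abs(con[chosen])
            out$chosen_stimulus[k] <- chosen
          } else {
            modes <- away_modes(az, "divided")
            mu <- if (length(modes) > 1L) modes[sample.int(length(modes), 1L)]
                  else modes
            c_eff <- max(abs(con))
          }
          m_sqrt <- params$timing_mean_sqrt + crab_offsets[s] +
            params$timing_contrast_slope * (c_eff - 1)
          out$mode_used[k] <- mode_used
          out$escape_direction_deg[k] <- rvonmises_deg(1, mu, params$kappa)
          out$time_to_collision_s[k] <-
            max(rnorm(1, m_sqrt, params$timing_sd_sqrt), 0)^2
        }
        out$crab_id[k] <- sprintf("crab%03d", s)
        out$sex[k] <- sexes[s]
        out$order[k] <- j
        out$treatment[k] <- name
        out$stim_azimuth_1[k] <- az[1]
        if (length(az) > 1L) out$stim_azimuth_2[k] <- az[2]
        out$contrast_1[k] <- con[1]
        if (length(con) > 1L) out$contrast_2[k] <- con[2]
        out$body_orientation_deg[k] <- body
        out$responded[k] <- responded
      }
    }
    tibble::as_tibble(out)
  })
}
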