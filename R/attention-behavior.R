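# Behavioural discrimination of selective vs divided attention.
#
# Pipeline (per paired treatment, against the matching single treatment,
# all angles already in the stimulus frame with the first stimulus at 0):
#   1. multimodal transform (x4 for 90-deg pairs, x2 for 180-deg pairs);
#      the transform maps both selective modes onto a common target and the
#      divided mode onto the opposite target, so the transformed mean
#      direction separates the hypotheses;
#   2. Rayleigh tests pre and post transform;
#   3. bootstrap CIs on the transformed mean directions, single vs paired;
#   4. dispersion comparison (Rao-type) single vs paired;
#   5. sector test on the 45-deg green/red scheme (90-deg pairs only).

#' Predicted escape directions under an attention hypothesis
#'
#' Selective attention predicts one escape mode directly away from each
#' stimulus; divided attention predicts a single mode at the circular mean
#' of the away-directions (the direction maximising distance from both).
#' For antipodal stimuli the divided prediction degenerates to the two
#' orthogonal directions.
#'
#' @param azimuths Stimulus approach azimuths (deg), length 1 or 2.
#' @param hypothesis `"selective"` or `"divided"`.
#' @return A tibble with columns `hypothesis` and `mode_deg`.
#' @export
#' @examples
#' predict_directions(c(0, 270), "selective")  # 180 and 90
#' predict_directions(c(0, 270), "divided")    # 135
predict_directions <- function(azimuths,
                               hypothesis = c("selective", "divided")) {
  hypothesis <- match.arg(hypothesis)
  tibble::tibble(hypothesis = hypothesis,
                 mode_deg = away_modes(norm_angle(azimuths), hypothesis))
}

# Internal: separation (deg) of a two-stimulus treatment row.
treatment_separation <- function(az1, az2) {
  if (is.na(az2)) return(NA_real_)
  abs(ang_diff(az2, az1))
}

#' Behavioural verdict: selective vs divided attention
#'
#' Applies the circular-statistics pipeline to an escape-trial table and
#' returns a verdict per paired treatment plus an overall verdict. The
#' transformed paired sample must be significantly directional (Rayleigh)
#' for a verdict; its transformed mean is then compared against the
#' transformed selective target (both selective modes map there) and the
#' transformed divided target (180 deg away), and the closer target wins.
#' Fewer than `min_n` responding trials in a group, or a non-directional
#' transformed sample, yields `"inconclusive"`.
#'
#' @param trials Escape-trial tibble (see [gen_escape_trials()] /
#'   [read_trials()]); must contain at least one single and one paired
#'   treatment.
#' @param alpha Significance level for the Rayleigh gate.
#' @param min_n Minimum responding trials per group (default 10).
#' @param n_boot Bootstrap resamples for mean-direction CIs.
#' @param n_perm Permutations for the sector test.
#' @param seed Optional integer seed for the resampling steps.
#' @return An object of class `attention_report`: a list with `verdict`,
#'   `per_treatment` (tibble of supporting statistics) and `alpha`.
#'   [tidy()] returns the per-treatment table, [glance()] a one-row
#'   summary.
#' @export
behavioral_decision <- function(trials, alpha = 0.05, min_n = 10,
                                n_boot = 2000, n_perm = 5000, seed = NULL) {
  resp <- dplyr::filter(trials, .data$responded,
                        !is.na(.data$escape_direction_deg))
  info <- dplyr::distinct(trials, .data$treatment, .data$stim_azimuth_1,
                          .data$stim_azimuth_2)
  info$separation <- purrr::map2_dbl(info$stim_azimuth_1,
                                     info$stim_azimuth_2,
                                     treatment_separation)
  singles <- info$treatment[is.na(info$separation)]
  paired <- info$treatment[!is.na(info$separation)]
  if (length(singles) < 1L || length(paired) < 1L) {
    abort("Need at least one single and one paired treatment.",
          class = "loomattend_invalid_input")
  }
  # Single reference: pool all single treatments (equal-contrast designs
  # have one; contrast designs pool LC and HC).
  dir_single <- resp$escape_direction_deg[resp$treatment %in% singles]

  rows <- purrr::map(paired, function(trt) {
    row <- info[info$treatment == trt, ]
    sep <- row$separation
    m <- if (isTRUE(all.equal(sep, 90))) 4 else 2
    az <- c(row$stim_azimuth_1, row$stim_azimuth_2)
    dir_paired <- resp$escape_direction_deg[resp$treatment == trt]
    out <- tibble::tibble(
      treatment = trt, m = m, n_single = length(dir_single),
      n_paired = length(dir_paired), verdict = "inconclusive",
      rayleigh_p_raw = NA_real_, rayleigh_p_trans = NA_real_,
      rayleigh_p_single_trans = NA_real_,
      mean_trans_deg = NA_real_, dist_selective = NA_real_,
      dist_divided = NA_real_, means_ci_overlap = NA,
      rao_stat = NA_real_, rao_p = NA_real_,
      sector_p = NA_real_, prop_green_single = NA_real_,
      prop_green_paired = NA_real_
    )
    if (length(dir_paired) < min_n || length(dir_single) < min_n) {
      warn(sprintf("Treatment %s: fewer than %d responding trials; inconclusive.",
                   trt, min_n))
      return(out)
    }
    t_paired <- transform_multimodal(dir_paired, m)
    t_single <- transform_multimodal(dir_single, m)
    ray_raw <- rayleigh_test(dir_paired)
    ray_t <- rayleigh_test(t_paired)
    ray_s <- rayleigh_test(t_single)
    out$rayleigh_p_raw <- ray_raw$p.value
    out$rayleigh_p_trans <- ray_t$p.value
    out$rayleigh_p_single_trans <- ray_s$p.value
    # transformed targets: both selective modes map to m*(az1+180); the
    # divided mode maps 180 deg away from it
    target_sel <- norm_angle(m * (az[1] + 180))
    target_div <- norm_angle(target_sel + 180)
    sum_t <- circ_summary(t_paired)
    out$mean_trans_deg <- sum_t$mean_deg
    if (!sum_t$undefined) {
      out$dist_selective <- abs(ang_diff(sum_t$mean_deg, target_sel))
      out$dist_divided <- abs(ang_diff(sum_t$mean_deg, target_div))
    }
    ci_s <- bootstrap_direction_ci(t_single, n_boot = n_boot, seed = seed)
    ci_p <- bootstrap_direction_ci(t_paired, n_boot = n_boot,
                                   seed = if (is.null(seed)) NULL else seed + 1L)
    out$means_ci_overlap <- arcs_overlap(ci_s, ci_p)
    rao <- tryCatch(rao_dispersion_test(list(t_single, t_paired)),
                    error = function(e) NULL)
    if (!is.null(rao)) {
      out$rao_stat <- rao$statistic
      out$rao_p <- rao$p.value
    }
    if (m == 4) {
      # combined single distribution rotated to the paired frame: each
      # single escape counted relative to a 0-deg and a 270-deg approach
      combined_single <- norm_angle(c(dir_single,
                                      dir_single + ang_diff(az[2], az[1])))
      scheme <- sector_scheme(az)
      # with small, tightly concentrated samples one group can have no
      # green-or-red escapes at all; the sector comparison is then
      # unavailable and stays NA
      sec <- tryCatch(
        sector_proportion_test(
          sector_classify(combined_single, scheme),
          sector_classify(dir_paired, scheme),
          n_perm = n_perm,
          seed = if (is.null(seed)) NULL else seed + 2L),
        loomattend_invalid_input = function(e) NULL)
      if (!is.null(sec)) {
        out$sector_p <- sec$p.value
        out$prop_green_single <- sec$prop_green_single
        out$prop_green_paired <- sec$prop_green_paired
      }
    }
    if (ray_t$p.value < alpha && !sum_t$undefined) {
      out$verdict <- if (out$dist_selective <= out$dist_divided) {
        "selective"
      } else {
        "divided"
      }
    }
    out
  })
  per_treatment <- dplyr::bind_rows(rows)
  verdicts <- unique(per_treatment$verdict)
  overall <- if (length(verdicts) == 1L) verdicts else {
    decided <- setdiff(verdicts, "inconclusive")
    if (length(decided) == 1L) decided else "inconclusive"
  }
  structure(list(verdict = overall, per_treatment = per_treatment,
                 alpha = alpha),
            class = "attention_report")
}

# Internal: do two angular intervals (tibbles lower_deg/upper_deg) overlap?
arcs_overlap <- function(ci1, ci2) {
  in_arc <- function(x, lo, hi) {
    if (lo <= hi) x >= lo & x <= hi else x >= lo | x <= hi
  }
  any(in_arc(c(ci2$lower_deg, ci2$upper_deg, ci2$mean_deg),
             ci1$lower_deg, ci1$upper_deg)) ||
    any(in_arc(c(ci1$lower_deg, ci1$upper_deg, ci1$mean_deg),
               ci2$lower_deg, ci2$upper_deg))
}

#' Effect of body orientation on escape direction
#'
#' Groups the responding trials of each paired treatment into 90-degree
#' body-orientation bins (orientation of the first stimulus relative to the
#' crab's transverse axis, see [bin_orientation()]) and summarises escape
#' directions per bin: circular mean and resultant length, bootstrap CI and
#' Rayleigh test. Treatments with 180-degree separation are additionally
#' tested on the angle-doubled (axial) scale, the appropriate treatment for
#' antipodal escape modes.
#'
#' @param trials Escape-trial tibble.
#' @param min_n Bins with fewer responding trials are flagged and not
#'   tested.
#' @param n_boot Bootstrap resamples per bin.
#' @param seed Optional integer seed.
#' @return Tibble with one row per (treatment, bin): `n`, `lateral_stimulus`
#'   (1 or 2, which stimulus lies on the lateral axis), `mean_deg`, `rho`,
#'   `ci_lower`, `ci_upper`, `rayleigh_p`, `rayleigh_p_axial`, `tested`.
#' @export
orientation_effect <- function(trials, min_n = 5, n_boot = 1000,
                               seed = NULL) {
  resp <- dplyr::filter(trials, .data$responded,
                        !is.na(.data$escape_direction_deg),
                        !is.na(.data$stim_azimuth_2))
  if (nrow(resp) == 0L) {
    abort("No responding paired trials with body orientation.",
          class = "loomattend_invalid_input")
  }
  # orientation of stimulus 1 relative to the transverse axis: 0 when the
  # stimulus lies on the crab's lateral axis
  resp$theta_lat <- norm_angle(resp$stim_azimuth_1 -
                                 (resp$body_orientation_deg + 90))
  resp$orientation_bin <- bin_orientation(resp$theta_lat)
  resp %>%
    dplyr::group_by(.data$treatment, .data$orientation_bin) %>%
    dplyr::group_map(function(df, key) {
      sep <- treatment_separation(df$stim_azimuth_1[1], df$stim_azimuth_2[1])
      axial <- isTRUE(all.equal(sep, 180))
      lateral_stim <- if (key$orientation_bin %in%
                            c("lateral_0", "lateral_180")) 1L else 2L
      n <- nrow(df)
      out <- tibble::tibble(
        treatment = key$treatment, orientation_bin = key$orientation_bin,
        n = n, lateral_stimulus = lateral_stim, tested = n >= min_n,
        mean_deg = NA_real_, rho = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_, rayleigh_p = NA_real_,
        rayleigh_p_axial = NA_real_
      )
      if (n < min_n) return(out)
      a <- df$escape_direction_deg
      cs <- circ_summary(a, axial = axial)
      out$mean_deg <- cs$mean_deg
      out$rho <- cs$rho
      out$rayleigh_p <- rayleigh_test(a)$p.value
      if (axial) out$rayleigh_p_axial <- rayleigh_test(a, axial = TRUE)$p.value
      if (n >= 8L && !isTRUE(cs$undefined)) {
        ci <- suppressWarnings(
          bootstrap_direction_ci(a, n_boot = n_boot, seed = seed,
                                 axial = axial))
        out$ci_lower <- ci$lower_deg
        out$ci_upper <- ci$upper_deg
      }
      out
    }) %>%
    dplyr::bind_rows()
}

#' @export
print.attention_report <- function(x, ...) {
  cat("<attention_report>\n")
  cat("  behavioural verdict:", x$verdict, "\n")
  cat("  per-treatment:\n")
  print(x$per_treatment[, c("treatment", "verdict", "rayleigh_p_trans",
                            "dist_selective", "dist_divided")])
  invisible(x)
}

#' @export
#' @method tidy attention_report
tidy.attention_report <- function(x, ...) x$per_treatment

#' @export
#' @method glance attention_report
glance.attention_report <- function(x, ...) {
  tibble::tibble(verdict = x$verdict,
                 n_treatments = nrow(x$per_treatment),
                 alpha = x$alpha)
}
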