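#' Define a simulated looming stimulus
#'
#' A looming stimulus is a dark disk expanding on a display so as to mimic an
#' object of fixed physical diameter approaching the animal at constant speed
#' on a direct collision course. The behavioural experiments emulate a 30 mm
#' object approaching at 200 mm/s from 5000 mm (initial subtense 0.34 deg);
#' the electrophysiology experiments a 30 mm object at 90 mm/s from 1000 mm
#' (initial subtense 1.7 deg).
#'
#' @param diameter_mm Object diameter (mm), > 0.
#' @param speed_mm_s Constant approach speed (mm/s), >= 0.
#' @param start_distance_mm Starting distance (mm), > `diameter_mm / 2`.
#' @param contrast Weber contrast of the disk against the background, a
#'   fraction in `[-1, 0]` (dark stimuli; -1 is black on the background).
#' @param azimuth_deg Approach azimuth in the animal-centred frame, degrees
#'   in `[0, 360)`.
#' @param elevation_deg Elevation of the stimulus centre above the visual
#'   horizon, degrees.
#' @return An object of class `looming_stimulus` (a named list).
#' @export
#' @examples
#' looming_stimulus()                        # behavioural default
#' looming_stimulus(speed_mm_s = 90, start_distance_mm = 1000)  # ephys
looming_stimulus <- function(diameter_mm = 30, speed_mm_s = 200,
                             start_distance_mm = 5000, contrast = -1,
                             azimuth_deg = 0, elevation_deg = 15) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0) {
    abort("`diameter_mm` must be > 0.", class = "loomattend_invalid_parameter")
  }
  if (!is.numeric(speed_mm_s) || speed_mm_s < 0) {
    abort("`speed_mm_s` must be >= 0.", class = "loomattend_invalid_parameter")
  }
  if (start_distance_mm <= diameter_mm / 2) {
    abort("`start_distance_mm` must exceed the object radius.",
          class = "loomattend_invalid_parameter")
  }
  if (contrast < -1 || contrast > 0) {
    abort("`contrast` must lie in [-1, 0] (dark stimuli).",
          class = "loomattend_invalid_parameter")
  }
  structure(
    list(diameter_mm = diameter_mm, speed_mm_s = speed_mm_s,
         start_distance_mm = start_distance_mm, contrast = contrast,
         azimuth_deg = norm_angle(azimuth_deg), elevation_deg = elevation_deg),
    class = "looming_stimulus"
  )
}

#' @export
print.looming_stimulus <- function(x, ...) {
  cat(sprintf(
    "<looming_stimulus> %g mm disk, %g mm/s from %g mm (collision in %s s)\n",
    x$diameter_mm, x$speed_mm_s, x$start_distance_mm,
    if (x$speed_mm_s > 0) format(round(x$start_distance_mm / x$speed_mm_s, 3))
    else "Inf"))
  cat(sprintf("  azimuth %g deg, elevation %g deg, Weber contrast %g%%\n",
              x$azimuth_deg, x$elevation_deg, 100 * x$contrast))
  invisible(x)
}

#' Time to collision of a looming stimulus
#'
#' @param stimulus A [looming_stimulus()].
#' @return Time (s) from stimulus onset to the predicted collision,
#'   `start_distance / speed`.
#' @export
#' @examples
#' collision_time(looming_stimulus())  # 25 s
collision_time <- function(stimulus) {
  stopifnot(inherits(stimulus, "looming_stimulus"))
  if (stimulus$speed_mm_s <= 0) {
    abort("Collision time undefined for non-positive approach speed.",
          class = "loomattend_invalid_parameter")
  }
  stimulus$start_distance_mm / stimulus$speed_mm_s
}

#' Angular diameter of a looming stimulus
#'
#' Full angular subtense of the disk at a given time to collision, using the
#' exact form `2 * atan((D/2) / (v * tau))`. Once the simulated object reaches
#' the eye (`v * tau <= D/2`) the subtense saturates at 180 degrees, mirroring
#' a stimulus that has filled the display.
#'
#' @param stimulus A [looming_stimulus()].
#' @param tau Time to collision (s), >= 0; vectorised.
#' @return Angular diameter in degrees, in `(0, 180]`.
#' @export
#' @examples
#' angular_diameter(looming_stimulus(), 25)   # 0.34 deg at onset
angular_diameter <- function(stimulus, tau) {
  stopifnot(inherits(stimulus, "looming_stimulus"))
  if (any(tau < 0)) {
    abort("`tau` must be >= 0.", class = "loomattend_invalid_parameter")
  }
  R <- stimulus$diameter_mm / 2
  d <- stimulus$speed_mm_s * tau
  ifelse(d <= R, 180, rad2deg(2 * atan(R / d)))
}

#' Angular expansion rate of a looming stimulus
#'
#' Analytic time derivative of [angular_diameter()]:
#' `2 * R * v / (d^2 + R^2)` radians/s with `R = D/2`, `d = v * tau`,
#' returned in deg/s. Zero once the subtense has saturated at 180 degrees,
#' and zero for a stationary object.
#'
#' @inheritParams angular_diameter
#' @param tau Time to collision (s), > 0; vectorised.
#' @return Expansion rate in deg/s.
#' @export
expansion_rate <- function(stimulus, tau) {
  stopifnot(inherits(stimulus, "looming_stimulus"))
  if (any(tau <= 0)) {
    abort("`tau` must be > 0.", class = "loomattend_invalid_parameter")
  }
  R <- stimulus$diameter_mm / 2
  v <- stimulus$speed_mm_s
  d <- v * tau
  ifelse(d <= R, 0, rad2deg(2 * R * v / (d^2 + R^2)))
}

#' Weber contrast
#'
#' `(stim - bg) / bg`; -1 (i.e. -100%) for a black stimulus on any background.
#'
#' @param stim_level Stimulus luminance (arbitrary linear units).
#' @param bg_level Background luminance, > 0.
#' @return Dimensionless contrast fraction.
#' @export
#' @examples
#' weber_contrast(0, 0.5)    # -1
#' weber_contrast(0.3, 0.5)  # -0.4
weber_contrast <- function(stim_level, bg_level) {
  if (any(bg_level <= 0)) {
    abort("`bg_level` must be > 0.", class = "loomattend_invalid_parameter")
  }
  (stim_level - bg_level) / bg_level
}

#' Display linearisation look-up table
#'
#' Given the measured radiance of a display at each digital level, computes
#' the look-up table that makes emitted radiance linear in the requested
#' level: entry `k` of the LUT is the display level whose measured radiance
#' is closest to the radiance a perfectly linear display would emit at level
#' `k`. Endpoints are preserved.
#'
#' @param radiance Numeric vector of measured radiances, one per display
#'   level (level `0` to `length(radiance) - 1`), monotone non-decreasing.
#' @return A tibble with columns `level` (requested linear level) and
#'   `display_level` (level to drive the display with).
#' @export
#' @examples
#' linearization_lut(seq(0, 1, length.out = 256))  # identity
linearization_lut <- function(radiance) {
  if (length(radiance) < 2L) {
    abort("Need radiance at two or more display levels.",
          class = "loomattend_data_error")
  }
  if (any(diff(radiance) < 0)) {
    abort("Measured radiance must be monotone non-decreasing in level.",
          class = "loomattend_data_error")
  }
  if (max(radiance) == min(radiance)) {
    abort("Constant radiance: display output does not depend on level.",
          class = "loomattend_data_error")
  }
  levels <- seq_along(radiance) - 1L
  target <- seq(radiance[1L], radiance[length(radiance)],
                length.out = length(radiance))
  # invert the (possibly flat-in-places) measured curve
  display <- approx(x = radiance, y = levels, xout = target,
                    ties = "ordered")$y
  tibble::tibble(level = levels, display_level = as.integer(round(display)))
}

#' Stimulus trace: subtense and expansion rate over the approach
#'
#' Tabulates the looming geometry on a uniform time-to-collision grid from
#' stimulus onset down to (but excluding) collision.
#'
#' @param stimulus A [looming_stimulus()].
#' @param dt Grid step (s).
#' @return A tibble with columns `time_to_collision_s`,
#'   `angular_diameter_deg`, `expansion_rate_deg_s`, ordered by decreasing
#'   time to collision.
#' @export
#' @examples
#' head(stimulus_trace(looming_stimulus(), dt = 0.5))
stimulus_trace <- function(stimulus, dt = 0.01) {
  stopifnot(inherits(stimulus, "looming_stimulus"), dt > 0)
  tc <- collision_time(stimulus)
  tau <- seq(tc, dt, by = -dt)
  tibble::tibble(
    time_to_collision_s = tau,
    angular_diameter_deg = angular_diameter(stimulus, tau),
    expansion_rate_deg_s = expansion_rate(stimulus, tau)
  )
}
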