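# Circular-statistics primitives, implemented from first principles.
# Angles are degrees in [0, 360) throughout the public interface.

#' Circular summary: mean direction and mean resultant length
#'
#' Vector-averages a sample of directions. Axial samples (directions defined
#' only up to 180 degrees) are doubled modulo 360 before averaging and the
#' mean is halved back, the standard angle-doubling treatment.
#'
#' @param angles Numeric vector of directions in degrees.
#' @param axial Treat the sample as axial data?
#' @return A one-row tibble with columns `n`, `mean_deg`, `rho` and
#'   `undefined` (TRUE when the resultant length is numerically zero, in
#'   which case the mean direction is meaningless and set to `NA`).
#' @export
#' @examples
#' circ_summary(c(0, 90))         # mean 45, rho = cos(45 deg)
#' circ_summary(c(0, 180))        # antipodal: undefined mean, rho 0
#' circ_summary(c(0, 180), axial = TRUE)
circ_summary <- function(angles, axial = FALSE) {
  if (length(angles) < 1L || anyNA(angles)) {
    abort("Need at least one non-missing angle.",
          class = "loomattend_invalid_input")
  }
  a <- norm_angle(angles)
  work <- if (axial) norm_angle(2 * a) else a
  m <- circ_moments(work)
  undefined <- m$rho < 1e-12
  mean_deg <- if (undefined) NA_real_ else if (axial) m$mean_deg / 2 else m$mean_deg
  tibble::tibble(n = length(a), mean_deg = mean_deg, rho = m$rho,
                 undefined = undefined)
}

#' Multimodal-to-unimodal angle transform
#'
#' Multiplies raw angles by `m` and reduces modulo 360. With `m = 4` the two
#' selective-escape modes expected for stimuli 90 degrees apart collapse onto
#' one common mode; with `m = 2` the antipodal modes expected for stimuli 180
#' degrees apart collapse likewise (the usual axial-data doubling).
#'
#' @param angles Directions in degrees.
#' @param m Integer multiplier; 2 and 4 are the conventional choices, other
#'   values are accepted with a warning.
#' @return Transformed angles in `[0, 360)`.
#' @export
#' @examples
#' transform_multimodal(c(180, 90), 4)  # both -> 0
#' transform_multimodal(180, 2)         # 0
transform_multimodal <- function(angles, m) {
  if (!m %in% c(2, 4)) {
    warn(sprintf("Multiplier m = %s is unconventional; 2 or 4 expected.", m))
  }
  norm_angle(m * angles)
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of directions against the uniform null. The statistic is
#' `Z = n * rho^2`; the p-value uses the standard series approximation
#' `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clipped to `[0, 1]`.
#'
#' @param angles Directions in degrees (n >= 2; the approximation is intended
#'   for n >= 4).
#' @param axial Double the angles first (axial data)?
#' @return An object of class `circ_htest` with elements `statistic`,
#'   `p.value`, `n`, `rho`, `method`. Use [tidy()] for a tibble.
#' @export
#' @examples
#' rayleigh_test(rep(90, 10))$p.value          # tiny
#' rayleigh_test(seq(0, 330, by = 30))$p.value # ~1 on a uniform grid
rayleigh_test <- function(angles, axial = FALSE) {
  n <- length(angles)
  if (n < 2L || anyNA(angles)) {
    abort("Rayleigh test needs >= 2 non-missing angles.",
          class = "loomattend_invalid_input")
  }
  a <- if (axial) norm_angle(2 * angles) else norm_angle(angles)
  rho <- circ_moments(a)$rho
  Z <- n * rho^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  structure(
    list(statistic = Z, p.value = min(max(p, 0), 1), n = n, rho = rho,
         method = "Rayleigh test of circular uniformity"),
    class = "circ_htest"
  )
}

#' Rao-type test for homogeneity of circular dispersions
#'
#' Chi-square test that k circular samples share a common dispersion,
#' following Rao's (1967) delta-method construction: each sample's dispersion
#' is summarised as `1 - r` (r the mean resultant length), its sampling
#' variance is estimated from the sample variances and covariance of the
#' cosine and sine components, and the weighted between-group sum of squares
#' is referred to a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param samples A list of numeric vectors of directions in degrees, each of
#'   length >= 5.
#' @return A `circ_htest` with `statistic`, `df`, `p.value`, `dispersions`.
#' @export
#' @examples
#' a <- c(10, 20, 350, 5, 15, 30, 355)
#' rao_dispersion_test(list(a, a))$statistic  # 0: identical groups
rao_dispersion_test <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    abort("Need a list of >= 2 circular samples.",
          class = "loomattend_invalid_input")
  }
  if (any(vapply(samples, length, 1L) < 5L)) {
    abort("Every group needs n >= 5.", class = "loomattend_invalid_input")
  }
  comp <- lapply(samples, function(a) {
    th <- deg2rad(norm_angle(a))
    n <- length(th)
    x <- cos(th); y <- sin(th)
    xb <- mean(x); yb <- mean(y)
    r <- sqrt(xb^2 + yb^2)
    # delta-method variance of r from the covariance of (mean cos, mean sin)
    vr <- (xb^2 * var(x) + 2 * xb * yb * stats::cov(x, y) + yb^2 * var(y)) /
      (n * max(r^2, 1e-300))
    list(d = 1 - r, v = vr)
  })
  d <- vapply(comp, `[[`, 1, "d")
  v <- vapply(comp, `[[`, 1, "v")
  if (any(v <= 0)) {
    abort("Degenerate sample (zero dispersion variance); test undefined.",
          class = "loomattend_invalid_input")
  }
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  stat <- sum(w * (d - dbar)^2)
  df <- length(samples) - 1L
  structure(
    list(statistic = stat, df = df,
         p.value = pchisq(stat, df, lower.tail = FALSE),
         dispersions = d, n = vapply(samples, length, 1L),
         method = "Rao-type chi-square test of dispersion homogeneity"),
    class = "circ_htest"
  )
}

#' Bootstrap confidence interval for a circular mean direction
#'
#' Percentile interval of resampled circular means, reported on the shortest
#' arc around the point estimate.
#'
#' @param angles Directions in degrees, n >= 8.
#' @param level Coverage level, default 0.95.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed (private RNG stream).
#' @param axial Axial data?
#' @return One-row tibble: `mean_deg`, `lower_deg`, `upper_deg`, `level`,
#'   `n_boot`. For a sample with numerically zero resultant length the mean
#'   is undefined and the full circle is returned with a warning.
#' @export
bootstrap_direction_ci <- function(angles, level = 0.95, n_boot = 2000,
                                   seed = NULL, axial = FALSE) {
  n <- length(angles)
  if (n < 8L) {
    abort("Bootstrap CI needs n >= 8.", class = "loomattend_invalid_input")
  }
  if (n_boot < 2L) {
    warn("n_boot < 2 gives a degenerate interval.")
  }
  est <- circ_summary(angles, axial = axial)
  if (isTRUE(est$undefined)) {
    warn("Mean direction undefined (resultant length ~ 0); full-circle interval.")
    return(tibble::tibble(mean_deg = NA_real_, lower_deg = 0, upper_deg = 360,
                          level = level, n_boot = as.integer(n_boot)))
  }
  a <- if (axial) norm_angle(2 * norm_angle(angles)) else norm_angle(angles)
  centre <- if (axial) norm_angle(2 * est$mean_deg) else est$mean_deg
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    th <- deg2rad(a)
    C <- colMeans(matrix(cos(th)[idx], nrow = n))
    S <- colMeans(matrix(sin(th)[idx], nrow = n))
    norm_angle(rad2deg(atan2(S, C)))
  })
  dev <- ang_diff(boots, centre)
  qs <- quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  scale <- if (axial) 2 else 1
  tibble::tibble(
    mean_deg = est$mean_deg,
    lower_deg = norm_angle(est$mean_deg + qs[1] / scale),
    upper_deg = norm_angle(est$mean_deg + qs[2] / scale),
    level = level, n_boot = as.integer(n_boot)
  )
}

#' Angular sector scheme for paired-stimulus escape directions
#'
#' Builds the labelled 45-degree sector scheme used to ask whether escapes
#' cluster at the direction that maximises distance from both stimuli
#' ("green", the divided-attention prediction) or in the outer flanks of the
#' two away-from-one-stimulus peaks ("red"). The central 45 degrees of each
#' away peak ("white") are excluded from the comparison.
#'
#' @param azimuths Two stimulus azimuths in degrees (default the canonical
#'   paired-90 frame, stimuli at 0 and 270).
#' @param width Sector width in degrees (default 45).
#' @return A tibble with columns `label`, `lo`, `hi` describing half-open
#'   intervals `[lo, hi)`.
#' @export
#' @examples
#' sector_scheme()
sector_scheme <- function(azimuths = c(0, 270), width = 45) {
  if (length(azimuths) != 2L) {
    abort("A sector scheme needs exactly two stimulus azimuths.",
          class = "loomattend_invalid_parameter")
  }
  away <- norm_angle(azimuths + 180)
  sep <- ang_diff(away[2], away[1])
  mid <- norm_angle(away[1] + sep / 2)        # divided-attention direction
  half <- width / 2
  # red flanks sit on the far side of each white sector from the green one
  red1 <- norm_angle(away[1] - sign(sep) * width)
  red2 <- norm_angle(away[2] + sign(sep) * width)
  tibble::tibble(
    label = c("green", "white", "white", "red", "red"),
    lo = norm_angle(c(mid, away[1], away[2], red1, red2) - half),
    hi = norm_angle(c(mid, away[1], away[2], red1, red2) + half)
  )
}

#' Classify angles into labelled sectors
#'
#' @param angles Directions in degrees.
#' @param scheme A sector scheme as returned by [sector_scheme()]; intervals
#'   are half-open `[lo, hi)`.
#' @return Character vector of labels; `"unlabeled"` for angles in no sector.
#' @export
#' @examples
#' sector_classify(c(135, 180, 90, 230), sector_scheme())
sector_classify <- function(angles, scheme) {
  a <- norm_angle(angles)
  out <- rep("unlabeled", length(a))
  for (i in seq_len(nrow(scheme))) {
    lo <- scheme$lo[i]; hi <- scheme$hi[i]
    inside <- if (lo <= hi) a >= lo & a < hi else a >= lo | a < hi
    out[inside] <- scheme$label[i]
  }
  out
}

#' Permutation test on the green-sector proportion
#'
#' Compares `P(green | green or red)` between two groups of sector labels by
#' permuting group membership; white and unlabeled escapes are excluded from
#' the comparison. When the number of distinct assignments is small
#' (`choose(n, n1) <= 20000`) the permutation distribution is enumerated
#' exactly; otherwise Monte Carlo with an add-one correction is used.
#'
#' @param labels_single,labels_paired Character vectors of sector labels for
#'   the two groups (as from [sector_classify()]).
#' @param n_perm Monte-Carlo permutations (ignored in the exact branch).
#' @param seed Optional integer seed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides automatically.
#' @return One-row tibble: `prop_green_single`, `prop_green_paired`,
#'   `p.value`, `exact`.
#' @export
sector_proportion_test <- function(labels_single, labels_paired,
                                   n_perm = 10000, seed = NULL, exact = NULL) {
  g1 <- labels_single[labels_single %in% c("green", "red")]
  g2 <- labels_paired[labels_paired %in% c("green", "red")]
  if (length(g1) == 0L && length(g2) == 0L) {
    # perfectly concentrated data: every escape in a white sector, nothing
    # to compare, no evidence of a difference
    return(tibble::tibble(prop_green_single = NA_real_,
                          prop_green_paired = NA_real_,
                          p.value = 1, exact = TRUE,
                          n_single = 0L, n_paired = 0L))
  }
  if (length(g1) == 0L || length(g2) == 0L) {
    abort("Each group needs at least one green-or-red label.",
          class = "loomattend_invalid_input")
  }
  x1 <- as.integer(g1 == "green")
  x2 <- as.integer(g2 == "green")
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  pooled <- c(x1, x2)
  obs <- abs(mean(x2) - mean(x1))
  eps <- 1e-12
  use_exact <- exact %||% (choose(n, n1) <= 20000)
  if (use_exact) {
    picks <- combn(n, n1)
    tot <- sum(pooled)
    stats_all <- apply(picks, 2, function(ix) {
      s1 <- sum(pooled[ix])
      abs((tot - s1) / n2 - s1 / n1)
    })
    p <- mean(stats_all >= obs - eps)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        ix <- sample.int(n, n1)
        s1 <- sum(pooled[ix])
        stat <- abs((sum(pooled) - s1) / n2 - s1 / n1)
        if (stat >= obs - eps) hits <- hits + 1L
      }
      (hits + 1) / (n_perm + 1)
    })
  }
  tibble::tibble(prop_green_single = mean(x1), prop_green_paired = mean(x2),
                 p.value = p, exact = use_exact,
                 n_single = n1, n_paired = n2)
}

#' Bin a body orientation into 90-degree sectors
#'
#' Converts an orientation angle into one of four 90-degree bins centred on
#' 0, 90, 180 and 270 degrees (half-open `[centre - 45, centre + 45)`). The
#' input convention is the angle between a stimulus azimuth and the animal's
#' transverse (lateral) axis, so the bins centred on 0 and 180 capture
#' stimuli aligned with the lateral axis and the bins centred on 90 and 270
#' capture stimuli aligned with the anterior-posterior (sagittal) axis.
#'
#' @param angles Orientations in degrees.
#' @return Factor with levels `lateral_0`, `sagittal_90`, `lateral_180`,
#'   `sagittal_270`.
#' @export
#' @examples
#' bin_orientation(c(0, 45, 200, 300))
bin_orientation <- function(angles) {
  a <- norm_angle(angles)
  centre <- (((a + 45) %/% 90) %% 4) * 90
  factor(c(`0` = "lateral_0", `90` = "sagittal_90", `180` = "lateral_180",
           `270` = "sagittal_270")[as.character(centre)],
         levels = c("lateral_0", "sagittal_90", "lateral_180", "sagittal_270"))
}

#' @export
print.circ_htest <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("statistic = %.4g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  cat(sprintf(", p-value = %.4g\n", x$p.value))
  invisible(x)
}

#' @export
#' @method tidy circ_htest
tidy.circ_htest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = if (is.null(x$df)) NA_integer_ else x$df,
    p.value = x$p.value,
    method = x$method
  )
}
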