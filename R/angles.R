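# Angle utilities. Public interface is in degrees; radians are internal.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise angles to [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @export
#' @examples
#' norm_angle(c(-90, 360, 725))
norm_angle <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

#' Signed shortest angular difference
#'
#' Difference `a - b` mapped to the shortest arc, in `(-180, 180]`.
#'
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Internal: mean direction (deg) and mean resultant length of angles in deg.
circ_moments <- function(angles_deg) {
  th <- deg2rad(angles_deg)
  C <- mean(cos(th))
  S <- mean(sin(th))
  list(mean_deg = norm_angle(rad2deg(atan2(S, C))), rho = sqrt(C^2 + S^2))
}

# Internal: von Mises sampler, Best & Fisher (1979) wrapping-rejection scheme.
# Returns n draws in degrees centred on mu_deg (scalar or length-n vector).
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return(norm_angle(runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.4))
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]
    if (length(f) > 0L) {
      take <- min(length(f), n - got)
      f <- f[seq_len(take)]
      theta <- sign(runif(take) - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[(got + 1L):(got + take)] <- theta
      got <- got + take
    }
  }
  norm_angle(rad2deg(out) + mu_deg)
}

# Internal: run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
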