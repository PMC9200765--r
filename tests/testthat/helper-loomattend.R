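# Shared fixtures, built in code.

behav_stimulus <- function(...) looming_stimulus(...)

ephys_stimulus <- function(contrast = -1, azimuth_deg = 0) {
  looming_stimulus(speed_mm_s = 90, start_distance_mm = 1000,
                   contrast = contrast, azimuth_deg = azimuth_deg)
}

# 50 deterministic two-group circular datasets; the frozen reference values
# in test-circstats.R were computed on exactly these draws.
make_rao_datasets <- function() {
  set.seed(20260921)
  lapply(1:50, function(i) {
    lapply(1:2, function(j) {
      n <- sample(20:60, 1)
      mu <- runif(1, 0, 360)
      sdd <- runif(1, 10, 80)
      (mu + rnorm(n, 0, sdd)) %% 360
    })
  })
}

# Homogeneous Poisson spike times on [t0, t1] at rate lambda.
rpois_train <- function(lambda, t0, t1) {
  n <- rpois(1, lambda * (t1 - t0))
  sort(runif(n, t0, t1))
}

# von Mises draws through the package sampler with a local seed.
rvm_deg <- function(n, mu, kappa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loomattend:::rvonmises_deg(n, mu, kappa)
}
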