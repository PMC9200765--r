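test_that("predicted modes follow the two hypotheses", {
  # single stimulus: both hypotheses predict straight away
  expect_equal(predict_directions(0, "selective")$mode_deg, 180)
  expect_equal(predict_directions(0, "divided")$mode_deg, 180)
  # paired 90: selective bimodal {180, 90}, divided unimodal 135
  expect_setequal(predict_directions(c(0, 270), "selective")$mode_deg,
                  c(180, 90))
  expect_equal(predict_directions(c(0, 270), "divided")$mode_deg, 135)
  # paired 180: selective {180, 0}, divided orthogonal pair {90, 270}
  expect_setequal(predict_directions(c(0, 180), "selective")$mode_deg,
                  c(180, 0))
  expect_setequal(predict_directions(c(0, 180), "divided")$mode_deg,
                  c(90, 270))
})

test_that("predicted modes rotate with the stimulus frame", {
  set.seed(3)
  for (i in 1:10) {
    az <- runif(1, 0, 360) + c(0, -90)
    delta <- runif(1, 0, 360)
    for (h in c("selective", "divided")) {
      base <- predict_directions(az, h)$mode_deg
      rot <- predict_directions(az + delta, h)$mode_deg
      expect_equal(sort(norm_angle(base + delta)), sort(rot),
                   tolerance = 1e-9)
    }
  }
})

test_that("behavioural verdict recovers the generating hypothesis at the
           degenerate concentration", {
  trts <- default_treatments(1)
  tr <- gen_escape_trials(trts, n_crabs = 40, trials_per_crab = 3,
                          params = behavior_params(kappa = 1e6,
                                                   response_prob = 1),
                          seed = 61)
  rep <- behavioral_decision(tr, seed = 62)
  expect_s3_class(rep, "attention_report")
  expect_equal(rep$verdict, "selective")
  expect_true(all(rep$per_treatment$verdict == "selective"))
  # sector test cannot reject equality when paired escapes sit exactly on
  # the selective modes (all white, but the combined tails are empty too)
  g <- glance(rep)
  expect_equal(g$verdict, "selective")
  expect_equal(nrow(tidy(rep)), 2L)
})

test_that("behavioural verdict is inconclusive for tiny samples", {
  trts <- default_treatments(1)
  tr <- gen_escape_trials(trts, n_crabs = 3, trials_per_crab = 3,
                          params = behavior_params(response_prob = 1),
                          seed = 63)
  w <- testthat::capture_warnings(rep <- behavioral_decision(tr, seed = 64))
  expect_true(any(grepl("fewer than", w)))
  expect_equal(rep$verdict, "inconclusive")
})

test_that("hypothesis recovery holds across seeds at the study scale", {
  # kappa = 8, ~40 responding trials per treatment; subset of the larger
  # acceptance sweep
  trts <- default_treatments(1)
  for (mode in c("selective", "divided")) {
    hits <- 0L
    for (s in 1:10) {
      tr <- gen_escape_trials(trts, n_crabs = 53, trials_per_crab = 3,
                              params = behavior_params(attention_mode = mode),
                              seed = 700 + s)
      v <- behavioral_decision(tr, n_boot = 500, n_perm = 1000,
                               seed = 800 + s)$verdict
      hits <- hits + (v == mode)
    }
    expect_gte(hits, 9L)
  }
})

test_that("the verdict degrades to inconclusive, not to the wrong answer,
           at low concentration", {
  trts <- default_treatments(1)
  wrong <- 0L
  inconc <- 0L
  for (s in 1:10) {
    tr <- gen_escape_trials(trts, n_crabs = 53, trials_per_crab = 3,
                            params = behavior_params(kappa = 0.5,
                                                     attention_mode = "selective"),
                            seed = 2300 + s)
    v <- behavioral_decision(tr, n_boot = 300, n_perm = 500,
                             seed = 2400 + s)$verdict
    wrong <- wrong + (v == "divided")
    inconc <- inconc + (v == "inconclusive")
  }
  expect_lte(wrong, 1L)
  expect_gte(inconc, 7L)
})

test_that("body orientation drives stimulus choice under lateral bias", {
  trts <- treatment_spec("Paired90", c(0, 270), c(-1, -1))
  tr <- gen_escape_trials(trts, n_crabs = 50, trials_per_crab = 40,
                          params = behavior_params(response_prob = 1,
                                                   lateral_bias_strength = 5,
                                                   kappa = 8),
                          seed = 71)
  oe <- orientation_effect(tr, seed = 72)
  expect_true(all(oe$tested))
  # bins where stimulus 1 (0 deg) is lateral: escapes away from it (180);
  # bins where stimulus 2 (270 deg) is lateral: escapes towards 90
  for (i in seq_len(nrow(oe))) {
    target <- if (oe$lateral_stimulus[i] == 1L) 180 else 90
    expect_lt(abs(ang_diff(oe$mean_deg[i], target)), 15)
  }
})

test_that("front-back paired-180 alignment shows axial but not raw
           directionality", {
  trts <- treatment_spec("Paired180", c(0, 180), c(-1, -1))
  tr <- gen_escape_trials(trts, n_crabs = 60, trials_per_crab = 30,
                          params = behavior_params(response_prob = 1,
                                                   lateral_bias_strength = 0,
                                                   kappa = 8),
                          seed = 73)
  oe <- orientation_effect(tr, seed = 74)
  # all bins behave alike here (50/50 choice): raw Rayleigh blind to the
  # antipodal mixture, axial Rayleigh sees it. The raw statistic is only
  # null-distributed under the exact mixture, so allow its nominal
  # false-positive rate across bins.
  expect_true(all(oe$rayleigh_p_axial < 1e-4))
  expect_gte(mean(oe$rayleigh_p > 0.05), 0.75)
  expect_true(all(oe$rayleigh_p > oe$rayleigh_p_axial))
})

test_that("unbiased choice splits evenly within every orientation bin", {
  trts <- treatment_spec("Paired90", c(0, 270), c(-1, -1))
  tr <- gen_escape_trials(trts, n_crabs = 40, trials_per_crab = 50,
                          params = behavior_params(response_prob = 1,
                                                   lateral_bias_strength = 0,
                                                   contrast_bias_strength = 0),
                          seed = 75)
  tr$theta_lat <- norm_angle(tr$stim_azimuth_1 -
                               (tr$body_orientation_deg + 90))
  tr$bin <- bin_orientation(tr$theta_lat)
  props <- tapply(tr$chosen_stimulus == 1, tr$bin, mean)
  ns <- table(tr$bin)
  for (b in names(props)) {
    expect_lt(abs(props[[b]] - 0.5), 3 * sqrt(0.25 / ns[[b]]))
  }
})

test_that("integration-rule recovery identifies max and sum populations", {
  # subset of the acceptance sweep (20-neuron populations)
  for (rule in c("max", "sum")) {
    want <- if (rule == "max") "select_stronger" else "sum"
    hits <- 0L
    for (s in 1:5) {
      pop <- gen_spike_population(
        20, spike_params(integration_rule = rule, spont_span = 5,
                         dt = 0.005),
        seed = 900 + s)
      m <- analyze_spike_trains(pop, dt = 0.01, pool_reps = TRUE,
                                window_per = "neuron")
      nd <- suppressWarnings(neural_decision(m, seed = 950 + s))
      hits <- hits + (nd$verdict == want)
      # a pure-max population must never be mistaken for summation
      if (rule == "max") expect_false(nd$verdict == "sum")
    }
    expect_gte(hits, 4L)
  }
})

test_that("identical single responses leave the integration rule
           undecidable", {
  # uniform receptive field: max and average predictions coincide
  pop <- gen_spike_population(8, spike_params(integration_rule = "max",
                                              spont_span = 5, dt = 0.005),
                              neuron_type = "MLG2", weight_jitter = 0,
                              seed = 81)
  m <- analyze_spike_trains(pop, dt = 0.01, pool_reps = TRUE,
                            window_per = "neuron")
  nd <- suppressWarnings(neural_decision(m, seed = 82))
  expect_equal(nd$verdict, "inconclusive")
})

test_that("neural decision validates its input", {
  pop <- gen_spike_population(3, spike_params(spont_span = 5, dt = 0.005),
                              n_reps = 1, seed = 83)
  m <- analyze_spike_trains(pop, dt = 0.01)
  expect_error(neural_decision(m), class = "loomattend_invalid_input")
})

test_that("timing comparison is exact for few subjects and null for
           identical groups", {
  # identical groups -> p ~ 1
  df <- tibble::tibble(
    crab_id = rep(sprintf("c%d", 1:6), each = 2),
    treatment = rep(c("A", "B"), 6),
    time_to_collision_s = rep(c(2.5, 2.5), 6)
  )
  r <- timing_comparison(df)
  expect_equal(r$p.value, 1)
  # agreement with brute-force sign-flip enumeration, 7 subjects
  set.seed(91)
  n_sub <- 7
  y <- matrix(runif(n_sub * 2, 1, 9), ncol = 2)
  df2 <- tibble::tibble(
    crab_id = rep(sprintf("c%d", 1:n_sub), each = 2),
    treatment = rep(c("A", "B"), n_sub),
    time_to_collision_s = as.vector(t(y))
  )
  r2 <- timing_comparison(df2)
  expect_equal(r2$method, "exact sign-flip")
  d <- sqrt(y[, 2]) - sqrt(y[, 1])
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
  brute <- mean(abs(flips %*% d) / n_sub >= abs(mean(d)) - 1e-12)
  expect_equal(r2$p.value, brute, tolerance = 1e-12)
  # Holm adjustment never decreases a p-value
  trts <- default_treatments(2)
  tr <- gen_escape_trials(trts, n_crabs = 12, params = behavior_params(),
                          seed = 92)
  r3 <- timing_comparison(dplyr::filter(tr, responded), seed = 93)
  ok <- !is.na(r3$p.value)
  expect_true(all(r3$p.holm[ok] >= r3$p.value[ok]))
})

test_that("a configured low-contrast delay is detected with high power", {
  # LC later than HC by 0.3 sqrt-s at 20 crabs (subset of the acceptance
  # power sweep)
  trts <- dplyr::bind_rows(
    treatment_spec("SingleHC", 0, -1),
    treatment_spec("SingleLC", 0, -0.4)
  )
  hits <- 0L
  for (s in 1:10) {
    tr <- gen_escape_trials(trts, n_crabs = 20, trials_per_crab = 2,
                            params = behavior_params(response_prob = 1),
                            seed = 1100 + s)
    r <- timing_comparison(dplyr::filter(tr, responded), seed = 1200 + s)
    hits <- hits + (r$p.value[1] < 0.05)
  }
  expect_gte(hits, 8L)
})
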