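# Neural integration-rule inference: does the response to paired stimuli
# look like the stronger single response (select-stronger), the sum of the
# two single responses, or their average?

#' Neural verdict: select-stronger vs sum vs average integration
#'
#' For every neuron with a complete treatment set (`Primary`, `Secondary`,
#' `Paired`), predicts the paired-stimulus peak and average spike rate under
#' each candidate rule applied to the two single-stimulus responses, and
#' scores each rule by its relative prediction error (averaged over the two
#' metrics, with the spontaneous-rate offset removed so rates compose
#' additively). The verdict is the rule with the smallest median error
#' across neurons, declared only when the bootstrap `level` CI (resampling
#' neurons) of the runner-up-minus-best error difference excludes zero;
#' otherwise `"inconclusive"`.
#'
#' @param metrics Tibble from [analyze_spike_trains()]: columns `neuron_id`,
#'   `treatment` (`Primary`/`Secondary`/`Paired`), `peak_rate`,
#'   `mean_rate_during_response`, `spont_mean`.
#' @param min_neurons Minimum neurons with complete treatment sets.
#' @param n_boot Bootstrap resamples over neurons.
#' @param level CI level for the tie rule.
#' @param seed Optional integer seed.
#' @return An object of class `neural_report`: list with `verdict` (one of
#'   `select_stronger`, `sum`, `average`, `inconclusive`), `errors` (per
#'   neuron x rule), `summary` (median error per rule with bootstrap CI of
#'   the gap to the best rule), `excluded` (neuron ids dropped and why).
#' @export
neural_decision <- function(metrics, min_neurons = 5, n_boot = 2000,
                            level = 0.95, seed = NULL) {
  needed <- c("Primary", "Secondary", "Paired")
  have <- metrics %>%
    dplyr::filter(.data$responded) %>%
    dplyr::group_by(.data$neuron_id) %>%
    dplyr::filter(all(needed %in% .data$treatment)) %>%
    dplyr::ungroup()
  excluded <- setdiff(unique(metrics$neuron_id), unique(have$neuron_id))
  if (length(excluded) > 0L) {
    warn(sprintf("%d neuron(s) excluded for incomplete treatment sets: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  neurons <- unique(have$neuron_id)
  if (length(neurons) < min_neurons) {
    abort(sprintf("Need >= %d neurons with complete treatment sets.",
                  min_neurons),
          class = "loomattend_invalid_input")
  }
  errs <- purrr::map(neurons, function(id) {
    df <- have[have$neuron_id == id, ]
    # median over repeat presentations: robust to the odd spurious onset
    get1 <- function(trt, col) median(df[[col]][df$treatment == trt])
    sp <- median(df$spont_mean)
    per_metric <- purrr::map(
      c(peak = "peak_rate", avg = "mean_rate_during_response"),
      function(col) {
        prim <- get1("Primary", col) - sp
        sec <- get1("Secondary", col) - sp
        obs <- get1("Paired", col) - sp
        pred <- c(select_stronger = max(prim, sec),
                  sum = prim + sec,
                  average = mean(c(prim, sec)))
        abs(pred - obs) / max(abs(obs), 1e-9)
      })
    # combine the two metrics by rank within each metric: ranks are immune
    # to the differing scales and window lengths of peak vs average rate
    rel <- (per_metric$peak + per_metric$avg) / 2
    rk <- (rank(per_metric$peak) + rank(per_metric$avg)) / 2
    tibble::tibble(neuron_id = id, rule = names(rel),
                   rel_error = unname(rel), rank = unname(rk))
  }) %>% dplyr::bind_rows()

  med <- errs %>%
    dplyr::group_by(.data$rule) %>%
    dplyr::summarise(median_error = median(.data$rel_error),
                     mean_rank = mean(.data$rank), .groups = "drop") %>%
    dplyr::arrange(.data$mean_rank, .data$median_error)
  best <- med$rule[1]
  runner <- med$rule[2]

  rmat <- tidyr::pivot_wider(errs[, c("neuron_id", "rule", "rank")],
                             names_from = "rule", values_from = "rank")
  # paired per-neuron rank difference: both rules are scored against the
  # same observed paired response, so the difference cancels shared noise
  d <- rmat[[runner]] - rmat[[best]]
  gaps <- with_seed(seed, {
    n <- length(d)
    vapply(seq_len(n_boot), function(b) {
      mean(d[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  qs <- quantile(gaps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  # identifiability gate: select-stronger and average make the same
  # prediction when no stimulus is consistently the stronger single input
  # (a uniform receptive field), so that pair of rules can only be
  # separated when the primary/secondary asymmetry is itself detectable
  signs <- vapply(neurons, function(id) {
    df <- have[have$neuron_id == id, ]
    p <- median(df$peak_rate[df$treatment == "Primary"])
    s <- median(df$peak_rate[df$treatment == "Secondary"])
    sign(p - s)
  }, numeric(1))
  asym_p <- stats::binom.test(sum(signs > 0), length(signs))$p.value
  confounded <- setequal(c(best, runner), c("select_stronger", "average")) &&
    asym_p >= 0.05
  decided <- qs[1] > 0 && !confounded
  structure(list(
    verdict = if (decided) best else "inconclusive",
    best_rule = best, runner_up = runner,
    gap_ci = qs, level = level, receptive_asymmetry_p = asym_p,
    errors = errs, summary = med,
    n_neurons = length(neurons), excluded = excluded
  ), class = "neural_report")
}

#' @export
print.neural_report <- function(x, ...) {
  cat("<neural_report>\n")
  cat(sprintf("  verdict: %s (best %s vs runner-up %s, gap CI [%.3g, %.3g])\n",
              x$verdict, x$best_rule, x$runner_up, x$gap_ci[1], x$gap_ci[2]))
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy neural_report
tidy.neural_report <- function(x, ...) x$summary

#' @export
#' @method glance neural_report
glance.neural_report <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, best_rule = x$best_rule,
                 runner_up = x$runner_up,
                 gap_ci_lower = x$gap_ci[1], gap_ci_upper = x$gap_ci[2],
                 n_neurons = x$n_neurons)
}

#' Subject-stratified permutation test on response timing
#'
#' Pairwise group comparisons of a (transformed) timing variable under a
#' permutation null that respects repeated measures: group labels are
#' permuted only within subject, preserving each subject's number of
#' observations per group. Behavioural timing should be supplied on the
#' square-root time-to-collision scale (`sqrt_transform = TRUE` does this);
#' neural onset times are used as-is. When every subject contributes one
#' observation to each of the two groups and there are at most `exact_limit`
#' such subjects, the sign-flip null is enumerated exactly. P-values across
#' contrasts are Holm-adjusted.
#'
#' @param data Tibble of observations.
#' @param value,group,subject Column names (strings) of the response, the
#'   grouping factor and the subject id.
#' @param sqrt_transform Square-root transform the response first?
#' @param n_perm Monte-Carlo permutations.
#' @param min_subjects Contrasts with fewer subjects are skipped.
#' @param exact_limit Maximum number of paired subjects for exhaustive
#'   sign-flip enumeration.
#' @param seed Optional integer seed.
#' @return Tibble with one row per pairwise contrast: `group1`, `group2`,
#'   `estimate` (mean difference, group2 minus group1), `p.value`, `p.holm`,
#'   `n_subjects`, `method`.
#' @export
timing_comparison <- function(data, value = "time_to_collision_s",
                              group = "treatment", subject = "crab_id",
                              sqrt_transform = TRUE, n_perm = 5000,
                              min_subjects = 3, exact_limit = 14,
                              seed = NULL) {
  df <- tibble::tibble(
    y = data[[value]], g = as.character(data[[group]]),
    s = as.character(data[[subject]])
  )
  df <- df[!is.na(df$y), ]
  if (sqrt_transform) {
    if (any(df$y < 0)) {
      abort("Negative values cannot be sqrt-transformed.",
            class = "loomattend_invalid_input")
    }
    df$y <- sqrt(df$y)
  }
  groups <- sort(unique(df$g))
  if (length(groups) < 2L) {
    abort("Need >= 2 groups.", class = "loomattend_invalid_input")
  }
  pairs <- combn(groups, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    sub <- df[df$g %in% pr, ]
    # subjects observed in both groups of this contrast
    keep <- sub %>%
      dplyr::group_by(.data$s) %>%
      dplyr::filter(length(unique(.data$g)) == 2L) %>%
      dplyr::ungroup()
    n_sub <- length(unique(keep$s))
    out <- tibble::tibble(group1 = pr[1], group2 = pr[2],
                          estimate = NA_real_, p.value = NA_real_,
                          n_subjects = n_sub, method = "skipped")
    if (n_sub < min_subjects) return(out)
    stat_fun <- function(d) {
      mean(d$y[d$g == pr[2]]) - mean(d$y[d$g == pr[1]])
    }
    obs <- stat_fun(keep)
    out$estimate <- obs
    counts <- keep %>%
      dplyr::count(.data$s, .data$g) %>%
      tidyr::pivot_wider(names_from = "g", values_from = "n",
                         values_fill = 0L)
    paired_once <- all(counts[[pr[1]]] == 1L) && all(counts[[pr[2]]] == 1L)
    if (paired_once && n_sub <= exact_limit) {
      # exact sign-flip: within-subject differences d_i, flip all sign
      # patterns
      wide <- keep %>%
        dplyr::select("s", "g", "y") %>%
        tidyr::pivot_wider(names_from = "g", values_from = "y")
      d <- wide[[pr[2]]] - wide[[pr[1]]]
      flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
      stats_all <- abs(flips %*% d) / n_sub
      out$p.value <- mean(stats_all >= abs(obs) - 1e-12)
      out$method <- "exact sign-flip"
    } else {
      out$p.value <- with_seed(seed, {
        split_idx <- split(seq_len(nrow(keep)), keep$s)
        hits <- 0L
        gvec <- keep$g
        for (b in seq_len(n_perm)) {
          gp <- gvec
          for (ix in split_idx) gp[ix] <- gvec[ix][sample.int(length(ix))]
          stat <- mean(keep$y[gp == pr[2]]) - mean(keep$y[gp == pr[1]])
          if (abs(stat) >= abs(obs) - 1e-12) hits <- hits + 1L
        }
        (hits + 1) / (n_perm + 1)
      })
      out$method <- "stratified permutation"
    }
    out
  }) %>% dplyr::bind_rows()
  tested <- !is.na(rows$p.value)
  rows$p.holm <- NA_real_
  rows$p.holm[tested] <- stats::p.adjust(rows$p.value[tested],
                                         method = "holm")
  rows
}
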