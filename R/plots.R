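# ggplot2 graphics for the main result types.

#' Plot an instantaneous firing-rate profile
#'
#' @param object A `rate_profile` from [estimate_rate()].
#' @param threshold Optional horizontal threshold line (Hz), e.g.
#'   `spont_mean + 2 * spont_sd`.
#' @param onset Optional onset time to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot rate_profile
autoplot.rate_profile <- function(object, threshold = NULL, onset = NULL,
                                  ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "time relative to predicted collision (s)",
                  y = "instantaneous firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  if (!is.null(onset) && !is.na(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, linetype = "dotted")
  }
  p
}

#' Circular plot of escape directions by treatment
#'
#' Rose-style histogram of escape directions of responding trials, facetted
#' by treatment, with the predicted selective (red) and divided (green)
#' modes overlaid for paired treatments.
#'
#' @param trials Escape-trial tibble.
#' @param binwidth Histogram bin width in degrees.
#' @return A ggplot.
#' @export
plot_escape_directions <- function(trials, binwidth = 15) {
  resp <- dplyr::filter(trials, .data$responded,
                        !is.na(.data$escape_direction_deg))
  preds <- resp %>%
    dplyr::distinct(.data$treatment, .data$stim_azimuth_1,
                    .data$stim_azimuth_2) %>%
    dplyr::rowwise() %>%
    dplyr::group_map(function(row, ...) {
      az <- c(row$stim_azimuth_1, row$stim_azimuth_2)
      az <- az[!is.na(az)]
      dplyr::bind_rows(
        dplyr::mutate(predict_directions(az, "selective"),
                      treatment = row$treatment),
        dplyr::mutate(predict_directions(az, "divided"),
                      treatment = row$treatment)
      )
    }) %>%
    dplyr::bind_rows()
  ggplot2::ggplot(resp, ggplot2::aes(x = .data$escape_direction_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(data = preds,
                        ggplot2::aes(xintercept = .data$mode_deg,
                                     colour = .data$hypothesis),
                        linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(selective = "firebrick",
                                            divided = "forestgreen")) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 270, by = 90)) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "escape direction (deg, stimulus frame)", y = NULL,
                  colour = "prediction") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus trace
#'
#' Angular subtense and expansion rate against time to collision.
#'
#' @param stimulus A [looming_stimulus()].
#' @param dt Grid step (s).
#' @return A ggplot.
#' @export
plot_stimulus_trace <- function(stimulus, dt = 0.05) {
  tr <- stimulus_trace(stimulus, dt = dt)
  long <- tidyr::pivot_longer(tr, -"time_to_collision_s",
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_to_collision_s,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time to collision (s)", y = NULL) +
    ggplot2::theme_minimal()
}
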