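# ggplot2 figures for scores, location accuracy, and psychometric fits.

#' Plot segmentation scores by participant, condition and test
#'
#' Precision, recall and F per participant and condition, with the
#' permutation-null 95% upper bound overlaid on the F panel when present.
#'
#' @param report Report tibble from [run_experiment()] (or a row-bound set
#'   of [score_segmentation()] results with `participant`, `condition`, and
#'   optionally `test`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_scores <- function(report) {
  stopifnot(is.data.frame(report))
  if (!"test" %in% names(report)) report$test <- "test"
  long <- tidyr::pivot_longer(
    report, cols = c("precision", "recall", "f_score"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, c("precision", "recall", "f_score"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$participant, y = .data$value,
                                          fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(test ~ measure) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if ("ci_high" %in% names(report)) {
    null_df <- dplyr::mutate(report, measure = factor("f_score", levels(long$measure)))
    p <- p + ggplot2::geom_errorbar(
      data = null_df,
      ggplot2::aes(x = .data$participant, ymin = .data$ci_high, ymax = .data$ci_high,
                   group = .data$condition),
      inherit.aes = FALSE, linetype = "dashed", width = 0.6)
  }
  p
}

#' Plot location-level accuracy by log frequency
#'
#' Proportion of correct gap decisions binned by the log frequency of the
#' governing word, split by boundary status, with Beta-posterior intervals
#' and a moving-average smoother.
#'
#' @param decisions Output of [classify_locations()].
#' @param n_bins Bins on log frequency.
#' @param smooth_window Moving-average window (log-frequency units); 0
#'   disables the smoother.
#' @return A ggplot object.
#' @export
plot_location_accuracy <- function(decisions, n_bins = 8L, smooth_window = 1.5) {
  binned <- bin_by_log_frequency(decisions, n_bins)
  binned$status <- ifelse(binned$is_boundary, "boundary", "word-internal")
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$log_freq_mid,
                                            y = .data$prop_correct,
                                            colour = .data$status)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "log word frequency", y = "proportion correct",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (smooth_window > 0) {
    sm <- decisions |>
      dplyr::mutate(status = ifelse(.data$is_boundary, "boundary", "word-internal")) |>
      dplyr::group_by(.data$status) |>
      dplyr::reframe(moving_average(.data$log_freq, as.numeric(.data$correct),
                                    window = smooth_window))
    p <- p + ggplot2::geom_line(data = sm,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$status))
  }
  p
}

#' @export
#' @method autoplot seglab_half_logit
autoplot.seglab_half_logit <- function(object, n_ranges = 4L, ...) {
  d <- object$data
  rng <- range(d$log_target_freq)
  breaks <- seq(rng[1], rng[2], length.out = n_ranges + 1L)
  obs <- d |>
    dplyr::mutate(bin = cut(.data$log_target_freq, breaks, include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(log_freq = mean(.data$log_target_freq),
                     accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
  grid <- tibble::tibble(log_target_freq = seq(rng[1], rng[2], length.out = 100))
  grid$accuracy <- predict(object, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$log_freq, y = .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$log_target_freq, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0.25, 1)) +
    ggplot2::labs(x = "log target frequency", y = "2AFC accuracy", size = "trials") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot seglab_permnull
autoplot.seglab_permnull <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(f = object$f_samples), ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_f, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "permuted F-score", y = "replicates") +
    ggplot2::theme_minimal()
}
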