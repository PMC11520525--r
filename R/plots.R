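#' Plot the time-error trajectories of a simulation log
#'
#' One line per device: total time error (ms) against reference time, with
#' applied synchronisations marked.
#'
#' @param object a `tagsync_log`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tagsync_log <- function(object, ...) {
  snap <- mutate(object$snapshots, T_error_ms = 1000 * .data$T_error_s,
                 t_h = .data$t_s / 3600)
  p <- ggplot2::ggplot(snap, ggplot2::aes(.data$t_h, .data$T_error_ms,
                                          colour = .data$device_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "reference time (h)", y = "T_error (ms)",
                  colour = "device") +
    ggplot2::theme_minimal()
  if (nrow(object$syncs) > 0) {
    p <- p + ggplot2::geom_vline(
      data = distinct(object$syncs, .data$reference_time_s),
      ggplot2::aes(xintercept = .data$reference_time_s / 3600),
      linetype = "dotted", colour = "grey40"
    )
  }
  p
}

#' Plot a fitted drift rate over its error trace
#'
#' @param object a `ppm_fit` from [fit_ppm()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ppm_fit <- function(object, ...) {
  d <- tibble(t_s = object$fit$model$tv, err_s = object$fit$model$ev)
  ggplot2::ggplot(d, ggplot2::aes(.data$t_s / 3600, .data$err_s * 1000)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept_s * 1000,
                         slope = object$ppm * 3.6,
                         colour = "firebrick") +
    ggplot2::labs(x = "reference time (h)", y = "T_error (ms)",
                  title = sprintf("fitted drift: %.3f ppm", object$ppm)) +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise relative time differences
#'
#' @param pairs a pairwise-difference table from
#'   [pairwise_relative_errors()].
#' @param binwidth_ms histogram bin width, ms.
#' @return a ggplot object.
#' @export
plot_pairwise_errors <- function(pairs, binwidth_ms = 5) {
  pairs <- as_tibble(pairs)
  stats <- median_mad(abs(pairs$delta_ms))
  ggplot2::ggplot(pairs, ggplot2::aes(.data$delta_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth_ms, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(
      x = "pairwise relative time difference (ms)", y = "count",
      title = sprintf("|median| %.1f ms (MAD %.1f, N = %d)",
                      abs(stats$median), stats$mad, stats$n)
    ) +
    ggplot2::theme_minimal()
}
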