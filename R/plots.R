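#' Plot a tracking trajectory
#'
#' Top view of the desired path, the true capsule trajectory and the
#' estimated trajectory, in millimetres.
#'
#' @param object A `capsnav_trajectory` from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capsnav_trajectory
#' @export
autoplot.capsnav_trajectory <- function(object, ...) {
  path <- attr(object, "path")
  pd <- tibble::tibble(x = 1e3 * path[, 1], y = 1e3 * path[, 2],
                       which = "desired path")
  td <- tibble::tibble(x = 1e3 * object$x, y = 1e3 * object$y,
                       which = "true trajectory")
  ed <- tibble::tibble(x = 1e3 * object$est_x, y = 1e3 * object$est_y,
                       which = "estimated trajectory")
  ggplot2::ggplot(dplyr::bind_rows(pd, td, ed),
                  ggplot2::aes(.data$x, .data$y, colour = .data$which,
                               linetype = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  linetype = NULL,
                  title = "Closed-loop tracking (top view)") +
    ggplot2::theme_minimal()
}

#' Plot tracking error over time
#'
#' @param log A `capsnav_trajectory`.
#' @return A ggplot object showing in-plane path error and localization
#'   error per tick, in millimetres.
#' @export
plot_tracking_error <- function(log) {
  d <- tidyr::pivot_longer(
    tibble::tibble(time = log$time,
                   `path error` = 1e3 * log$path_error_xy,
                   `localization error` = 1e3 * log$loc_error),
    -"time", names_to = "metric", values_to = "mm")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$mm,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "error (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery study
#'
#' Median, mean and 95th-percentile position-recovery error against the
#' sensor-noise level.
#'
#' @param object A `capsnav_recovery` from [recovery_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capsnav_recovery
#' @export
autoplot.capsnav_recovery <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "sigma", "median_error",
                  "mean_error", "p95_error"),
    -"sigma", names_to = "statistic", values_to = "mm")
  ggplot2::ggplot(d, ggplot2::aes(1e3 * .data$sigma, .data$mm,
                                  colour = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sensor noise SD (mT)", y = "position error (mm)",
                  colour = NULL, title = "Pose recovery vs. sensor noise") +
    ggplot2::theme_minimal()
}
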