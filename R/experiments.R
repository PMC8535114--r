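#' Default free-space tracking scenario
#'
#' Bundles the standard study conditions: default magnet, 6 x 6 sensor array,
#' ten-coil layout, U-shape path on the ROI centre plane, free space, and
#' the 5 mT / 50 mT/m command preset (`gamma` = 0.1 m) with 0.05 mT sensor
#' noise. `scenario_phantom()` swaps in the 7 mT / 70 mT/m preset and a
#' friction threshold, for tube-phantom style runs.
#'
#' @param noise_sigma Sensor noise SD, Tesla.
#' @return A named list with components `path`, `env`, `config`, `array`,
#'   `spec`, `controller`, ready for [run_closed_loop()] / [track_trials()].
#' @export
scenario_free_space <- function(noise_sigma = 5e-5) {
  list(path = generate_ushape_path(),
       env = sim_environment("free_space"),
       config = default_ema_config(),
       array = sensor_array(),
       spec = magnet_spec(),
       controller = list(F = 0.05, gamma = 0.1, noise_sigma = noise_sigma))
}

#' @rdname scenario_free_space
#' @export
scenario_phantom <- function(noise_sigma = 5e-5) {
  path <- generate_ushape_path()
  sc <- scenario_free_space(noise_sigma)
  sc$env <- sim_environment("tube", friction_threshold_force = 0.005,
                           tube_centerline = path, tube_radius = 0.008)
  sc$controller$F <- 0.07
  sc
}

#' Repeated seeded tracking trials
#'
#' Runs the closed-loop tracking scenario `n_trials` times with seeds
#' `base_seed, base_seed + 1, ...` and reports per-trial error statistics,
#' the in-silico analogue of repeating a manipulation trial. Both the
#' path-tracking error (perpendicular distance of the true position to the
#' desired polyline; in-plane, the headline metric) and the localization
#' error (true vs. estimated position) are summarized.
#'
#' @param scenario A scenario list as from [scenario_free_space()].
#' @param n_trials Number of repeats.
#' @param base_seed Seed of the first trial.
#' @return A tibble with one row per trial: `trial`, `seed`, `n_steps`,
#'   `mean_error`, `sd_error`, `max_error` (tracking, mm), `mean_error_3d`,
#'   `mean_loc_error`, `max_loc_error` (mm). The trajectory logs are in the
#'   `"logs"` attribute.
#' @examples
#' \donttest{
#' trials <- track_trials(scenario_free_space(), n_trials = 2, base_seed = 7)
#' trials$mean_error
#' }
#' @export
track_trials <- function(scenario, n_trials = 4L, base_seed = 1L) {
  logs <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    seed <- base_seed + t - 1L
    log <- run_closed_loop(scenario$path, scenario$env, scenario$config,
                           scenario$array, scenario$spec,
                           controller = scenario$controller, seed = seed)
    s <- attr(log, "summary")
    logs[[t]] <- log
    rows[[t]] <- tibble::tibble(
      trial = t, seed = seed, n_steps = s$n_steps,
      mean_error = s$mean_error_mm, sd_error = s$sd_error_mm,
      max_error = s$max_error_mm, mean_error_3d = s$mean_error_3d_mm,
      mean_loc_error = s$mean_loc_error_mm,
      max_loc_error = s$max_loc_error_mm
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "logs") <- logs
  out
}

#' Monte-Carlo pose-recovery study
#'
#' Isolates the localization pipeline from the control loop: draws random
#' poses in the ROI, synthesizes frames (with active coil currents, so the
#' compensation path is exercised), estimates each pose from a cold start,
#' and summarizes the recovery error per noise level.
#'
#' @param n_poses Poses per noise level.
#' @param sigmas Noise SDs to sweep, Tesla.
#' @param seed Integer seed (one stream for the whole study).
#' @param config,array,spec System description; defaults are the standard
#'   setup.
#' @param with_currents Drive random coil currents (within half the limit)
#'   during each read so compensation is active.
#' @param quantize Apply ADC quantization in the synthesized frames; disable
#'   to study the estimator without the ADC floor.
#' @return A `capsnav_recovery` tibble, one row per noise level:
#'   `sigma` (T), `median_error`, `mean_error`, `p95_error` (position, mm),
#'   `median_heading_error` (deg), `n`. Per-pose results are in the
#'   `"draws"` attribute.
#' @export
recovery_study <- function(n_poses = 100L, sigmas = c(0, 1e-5, 5e-5, 1e-4),
                           seed = 1L, config = default_ema_config(),
                           array = sensor_array(), spec = magnet_spec(),
                           with_currents = TRUE, quantize = TRUE) {
  if (n_poses < 1L) abort("`n_poses` must be >= 1")
  set.seed(seed)
  basis <- sensor_basis_for(config, array)
  roi <- config$roi
  draws <- vector("list", length(sigmas) * n_poses)
  k <- 0L
  for (sigma in sigmas) {
    for (i in seq_len(n_poses)) {
      pos <- c(stats::runif(1, roi$xlim[1], roi$xlim[2]),
               stats::runif(1, roi$ylim[1], roi$ylim[2]),
               stats::runif(1, roi$zlim[1], roi$zlim[2]))
      yaw <- stats::runif(1, -pi, pi)
      pitch <- stats::runif(1, -80, 80) * pi / 180
      pose <- magnet_pose(pos, heading_from_angles(yaw, pitch))
      currents <- if (with_currents) {
        stats::runif(10, -config$current_limit / 2, config$current_limit / 2)
      } else rep(0, 10)
      frame <- synth_sensor_frame(capsule_state(pose), currents, array, spec,
                                  basis, noise_sigma = sigma,
                                  quantize = quantize)
      est <- estimate_pose(frame, basis, array, spec, roi = roi)
      k <- k + 1L
      draws[[k]] <- tibble::tibble(
        sigma = sigma, draw = i,
        pos_error = vnorm(est$pose$position - pos),
        heading_error = acos(max(-1, min(1, sum(est$pose$heading *
                                                  pose$heading)))),
        converged = est$converged, cost = est$cost
      )
    }
  }
  per_draw <- dplyr::bind_rows(draws)
  out <- per_draw |>
    dplyr::group_by(.data$sigma) |>
    dplyr::summarise(
      median_error = 1e3 * median(.data$pos_error),
      mean_error = 1e3 * mean(.data$pos_error),
      p95_error = 1e3 * quantile(.data$pos_error, 0.95, names = FALSE),
      median_heading_error = 180 / pi * median(.data$heading_error),
      n = dplyr::n(), .groups = "drop")
  attr(out, "draws") <- per_draw
  class(out) <- c("capsnav_recovery", class(out))
  out
}

#' Tag external detection events with capsule poses
#'
#' Annotates an external event stream (e.g. detections from a video pipeline)
#' with the pose estimate at the nearest logged tick of a trajectory; on a
#' tie the earlier tick wins. Events outside the log's time span are
#' rejected with a reason.
#'
#' @param log A `capsnav_trajectory` from [run_closed_loop()].
#' @param events Data frame with columns `timestamp` (s) and `label`.
#' @return A tibble, one row per input event: `timestamp`, `label`,
#'   `accepted`, `reason`, `matched_time`, `x`, `y`, `z`, `yaw`, `pitch`
#'   (estimated pose at the matched tick; NA when rejected).
#' @export
tag_detection <- function(log, events) {
  if (!all(c("timestamp", "label") %in% names(events))) {
    abort("`events` needs `timestamp` and `label` columns")
  }
  span <- range(log$time)
  purrr::pmap_dfr(events[c("timestamp", "label")], function(timestamp, label) {
    if (timestamp < span[1] || timestamp > span[2]) {
      return(tibble::tibble(timestamp = timestamp, label = label,
                            accepted = FALSE,
                            reason = sprintf(
                              "timestamp outside log span [%.2f, %.2f] s",
                              span[1], span[2]),
                            matched_time = NA_real_, x = NA_real_,
                            y = NA_real_, z = NA_real_, yaw = NA_real_,
                            pitch = NA_real_))
    }
    d <- abs(log$time - timestamp)
    # ties (to within a nanosecond of clock rounding) resolve earlier
    i <- which(d <= min(d) + 1e-9)[1]
    tibble::tibble(timestamp = timestamp, label = label, accepted = TRUE,
                   reason = NA_character_, matched_time = log$time[i],
                   x = log$est_x[i], y = log$est_y[i], z = log$est_z[i],
                   yaw = log$est_yaw[i], pitch = log$est_pitch[i])
  })
}

## one-pass (Welford) mean/SD/max, used to cross-check the batch statistics
welford_stats <- function(x) {
  n <- 0L; mean <- 0; m2 <- 0; mx <- -Inf
  for (v in x) {
    n <- n + 1L
    d <- v - mean
    mean <- mean + d / n
    m2 <- m2 + d * (v - mean)
    if (v > mx) mx <- v
  }
  list(n = n, mean = mean, sd = if (n > 1) sqrt(m2 / (n - 1)) else NA_real_,
       max = mx)
}
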