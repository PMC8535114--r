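#' Write and read trajectory logs
#'
#' A trajectory log round-trips as plain CSV (one row per tick); the error
#' summary, seed and controller settings go to a JSON sidecar via
#' [write_trajectory_summary()].
#'
#' @param log A `capsnav_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly (`read_trajectory_csv()` returns a tibble).
#' @export
write_trajectory_csv <- function(log, file) {
  utils::write.csv(as.data.frame(log), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  tibble::as_tibble(utils::read.csv(file))
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_summary <- function(log, file) {
  out <- c(attr(log, "summary"),
           list(seed = attr(log, "seed"),
                controller = attr(log, "controller")))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write sensor frames to CSV
#'
#' One row per frame: timestamp, the ten coil currents, then one column per
#' sensor reading (Tesla).
#'
#' @param frames List of [sensor_frame()] objects.
#' @param file Output path.
#' @return `file` invisibly; `read_frames_csv()` returns the list of frames.
#' @export
write_frames_csv <- function(frames, file) {
  rows <- purrr::map_dfr(frames, function(f) {
    tibble::tibble(timestamp = f$timestamp,
                   !!!setNames(as.list(f$currents), paste0("i", 1:10)),
                   !!!setNames(as.list(f$readings),
                               paste0("s", seq_along(f$readings))))
  })
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(file) {
  d <- utils::read.csv(file)
  icols <- paste0("i", 1:10)
  scols <- grep("^s[0-9]+$", names(d), value = TRUE)
  lapply(seq_len(nrow(d)), function(r) {
    sensor_frame(as.numeric(d[r, scols]), as.numeric(d[r, icols]),
                 timestamp = d$timestamp[r])
  })
}

#' Serialize detection events to JSON
#'
#' @param tags Output of [tag_detection()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_detections_json <- function(tags, file) {
  jsonlite::write_json(tags, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' Read and write system configuration as YAML
#'
#' The run configuration (magnet, sensor array, coil list, ROI, current
#' limit) round-trips through a structured-text YAML file, so a study is
#' reproducible from (config, seed) alone. The magnet block accepts either
#' `volume` or `diameter`/`length`, and either `magnetization` or
#' `remanence`; the derivation is reported on load.
#'
#' @param config An [ema_config()].
#' @param array A [sensor_array()].
#' @param spec A [magnet_spec()].
#' @param file Path to the YAML file.
#' @param quiet Suppress the magnet-derivation message.
#' @return `write_system_yaml()`: `file` invisibly. `read_system_yaml()`: a
#'   list with `config`, `array`, `spec`.
#' @export
write_system_yaml <- function(config, array, spec, file) {
  coil_to_list <- function(co) {
    out <- list(shape = co$shape, center = co$center, axis = co$axis,
                turns = co$turns, label = co$label)
    if (co$shape == "circular") out$radius <- co$radius
    else { out$half_width <- co$half_width; out$half_height <- co$half_height }
    out
  }
  doc <- list(
    magnet = list(volume = spec$volume, magnetization = spec$magnetization),
    sensor_array = list(nx = NULL, positions = NULL,
                        sensitivity = array$sensitivity,
                        range_limit = array$range_limit,
                        supply_voltage = array$supply_voltage,
                        adc_bits = array$adc_bits),
    coils = lapply(config$coils, coil_to_list),
    roi = config$roi,
    current_limit = config$current_limit
  )
  # the default grid is regenerated from its parameters; custom layouts are
  # written out explicitly
  doc$sensor_array$positions <- apply(array$positions, 1, as.list,
                                      simplify = FALSE)
  yaml::write_yaml(doc, file, precision = 15)
  invisible(file)
}

#' @rdname write_system_yaml
#' @export
read_system_yaml <- function(file, quiet = FALSE) {
  doc <- yaml::read_yaml(file)
  m <- doc$magnet
  spec <- magnet_spec(
    diameter = m$diameter %||% 0.010, length = m$length %||% 0.012,
    volume = m$volume, remanence = m$remanence %||% 1.48,
    magnetization = m$magnetization)
  if (!quiet) {
    inform(sprintf(
      "magnet: V = %.4g m^3, |M| = %.4g A/m -> moment %.4g A m^2, BT %.4g T m^3",
      spec$volume, spec$magnetization, spec$moment, spec$dipole_strength))
  }
  sa <- doc$sensor_array
  array <- sensor_array(sensitivity = sa$sensitivity %||% 12.5,
                        range_limit = sa$range_limit %||% 0.169,
                        supply_voltage = sa$supply_voltage %||% 5.0,
                        adc_bits = sa$adc_bits %||% 16L)
  if (!is.null(sa$positions)) {
    array$positions <- do.call(rbind, lapply(sa$positions, unlist))
  }
  coils <- lapply(doc$coils, function(co) {
    coil_spec(co$shape, unlist(co$center), unlist(co$axis),
              radius = co$radius, half_width = co$half_width,
              half_height = co$half_height, turns = co$turns,
              label = co$label %||% "")
  })
  config <- ema_config(coils,
                       roi = lapply(doc$roi, unlist),
                       current_limit = doc$current_limit %||% 20)
  list(config = config, array = array, spec = spec)
}
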