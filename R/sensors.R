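#' Mono-axis Hall-sensor array
#'
#' Layout and analog model of the sensing board: a planar grid of linear
#' mono-axis Hall sensors measuring the board-normal (z) field component as a
#' ratiometric voltage around half the supply. Defaults describe a 6 x 6 grid
#' at 20 mm pitch spanning 100 mm x 100 mm at z = 0, 12.5 mV/mT sensitivity,
#' +/-169 mT range, 5 V supply, 16-bit ADC.
#'
#' @param nx,ny Grid size.
#' @param pitch Sensor pitch, metres.
#' @param center Board centre, 3-vector metres.
#' @param sensitivity Volts per Tesla (12.5 mV/mT = 12.5 V/T).
#' @param range_limit Measurable field magnitude, Tesla.
#' @param supply_voltage Supply, volts; zero field reads `supply/2`.
#' @param adc_bits ADC resolution over `0..supply_voltage`.
#' @return A `sensor_array` object; `positions` is an n x 3 matrix.
#' @export
sensor_array <- function(nx = 6L, ny = 6L, pitch = 0.020, center = c(0, 0, 0),
                         sensitivity = 12.5, range_limit = 0.169,
                         supply_voltage = 5.0, adc_bits = 16L) {
  if (nx * ny < 6L) abort("at least 6 sensors are required for 5-DOF identifiability")
  if (pitch <= 0) abort("`pitch` must be positive")
  xs <- (seq_len(nx) - (nx + 1) / 2) * pitch + center[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * pitch + center[2]
  g <- expand.grid(x = xs, y = ys)
  positions <- cbind(g$x, g$y, rep(center[3], nrow(g)))
  structure(
    list(positions = positions, axis = c(0, 0, 1), sensitivity = sensitivity,
         range_limit = range_limit, supply_voltage = supply_voltage,
         adc_bits = as.integer(adc_bits)),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d mono-axis sensors, %.1f mV/mT, +/-%.0f mT, %d-bit ADC\n",
              nrow(x$positions), x$sensitivity, # V/T numerically equals mV/mT
              1e3 * x$range_limit, x$adc_bits))
  invisible(x)
}

#' Sensor transfer function
#'
#' `voltage_from_field()` maps a field along the sensor axis to the output
#' voltage, `v = supply/2 + sensitivity * b`, clipping `b` at the range limit
#' first (clipped entries are flagged in the `"saturated"` attribute).
#' `field_from_voltage()` inverts the affine map; the round trip is the
#' identity inside the range.
#'
#' @param b Field along the sensor axis, Tesla (vectorized).
#' @param v Output voltage, volts (vectorized).
#' @param array A [sensor_array()].
#' @return Voltage (V) or field (T), same length as the input.
#' @export
voltage_from_field <- function(b, array) {
  saturated <- abs(b) > array$range_limit
  b_clip <- pmax(-array$range_limit, pmin(array$range_limit, b))
  v <- array$supply_voltage / 2 + array$sensitivity * b_clip
  attr(v, "saturated") <- saturated
  v
}

#' @rdname voltage_from_field
#' @export
field_from_voltage <- function(v, array) {
  (v - array$supply_voltage / 2) / array$sensitivity
}

#' One synchronized sensor read
#'
#' Container for a frame: the per-sensor measured field along the sensor axis
#' (Tesla), the coil currents active during the read, the timestamp, and the
#' per-sensor saturation flags.
#'
#' @param readings Numeric vector, Tesla, one entry per sensor.
#' @param currents Numeric 10-vector, amperes.
#' @param timestamp Seconds.
#' @param saturated Logical vector, same length as `readings`.
#' @return A `sensor_frame` object.
#' @export
sensor_frame <- function(readings, currents, timestamp = 0,
                         saturated = rep(FALSE, length(readings))) {
  if (length(currents) != 10L) abort("`currents` must have length 10")
  if (length(saturated) != length(readings)) {
    abort("`saturated` must match `readings` in length")
  }
  structure(list(readings = as.numeric(readings),
                 currents = as.numeric(currents),
                 timestamp = timestamp, saturated = saturated),
            class = "sensor_frame")
}
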