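#' Piezoelectric gyroscope and acquisition-chain parameters
#'
#' Describes the rate-to-voltage characteristic of a single-axis vibratory
#' gyroscope (Murata Gyrostar class) together with the A/D conversion and
#' downsampling stages of the acquisition chain. The defaults model a sensor
#' that maps 0 deg/s to 2.5 V and +/-90 deg/s to 4.5/0.5 V, saturating at the
#' rails, sampled by an 8-bit converter over 0-5 V at 2668 Hz and decimated
#' by 20 to an effective 133.4 Hz.
#'
#' @param rate_max Maximum measurable angular rate (deg/s); rates beyond
#'   `+/-rate_max` saturate at the corresponding voltage rail.
#' @param v_zero Output voltage at zero angular rate (V).
#' @param v_min,v_max Output voltage rails (V) reached at `-rate_max` and
#'   `+rate_max`.
#' @param adc_bits Resolution of the A/D converter (bits).
#' @param adc_range Full-scale input range of the converter, length-2 numeric
#'   (V).
#' @param fs_raw Raw sampling frequency of the converter (Hz).
#' @param downsample_factor Integer decimation factor applied after
#'   acquisition; the effective rate is `fs_raw / downsample_factor`.
#'
#' @return An object of class `gyro_spec` (a named list).
#' @examples
#' spec <- gyro_spec()
#' rate_to_voltage(c(-90, 0, 90), spec)
#' @export
gyro_spec <- function(rate_max = 90, v_zero = 2.5, v_min = 0.5, v_max = 4.5,
                      adc_bits = 8L, adc_range = c(0, 5),
                      fs_raw = 2668, downsample_factor = 20L) {
  spec <- list(
    rate_max = rate_max, v_zero = v_zero, v_min = v_min, v_max = v_max,
    adc_bits = as.integer(adc_bits), adc_range = as.numeric(adc_range),
    fs_raw = fs_raw, downsample_factor = as.integer(downsample_factor)
  )
  class(spec) <- "gyro_spec"
  validate_gyro_spec(spec)
  spec
}

validate_gyro_spec <- function(spec) {
  stopifnot(inherits(spec, "gyro_spec"))
  if (!(spec$v_min < spec$v_zero && spec$v_zero < spec$v_max)) {
    abort("gyro_spec requires v_min < v_zero < v_max.")
  }
  if (spec$rate_max <= 0) abort("gyro_spec requires rate_max > 0.")
  if (spec$adc_bits < 1L) abort("gyro_spec requires adc_bits >= 1.")
  if (length(spec$adc_range) != 2L || diff(spec$adc_range) <= 0) {
    abort("gyro_spec requires an increasing length-2 adc_range.")
  }
  if (spec$downsample_factor < 1L) {
    abort("gyro_spec requires downsample_factor >= 1.")
  }
  invisible(spec)
}

#' Convert angular rate to sensor output voltage
#'
#' Affine rate-to-voltage characteristic with saturation: within
#' `+/-rate_max` the output is `v_zero + rate * (v_max - v_zero) / rate_max`;
#' outside, the voltage clamps to the `v_min`/`v_max` rails, mimicking sensor
#' saturation. `voltage_to_rate()` inverts the affine segment (saturated
#' samples map to `+/-rate_max`).
#'
#' @param rate Numeric vector of angular rates (deg/s).
#' @param voltage Numeric vector of sensor voltages (V).
#' @param spec A [gyro_spec()].
#' @return Numeric vector of voltages (V), or rates (deg/s).
#' @examples
#' rate_to_voltage(0)     # 2.5 V
#' rate_to_voltage(150)   # clamped to 4.5 V
#' voltage_to_rate(rate_to_voltage(42.5))
#' @export
rate_to_voltage <- function(rate, spec = gyro_spec()) {
  validate_gyro_spec(spec)
  v <- spec$v_zero + rate * (spec$v_max - spec$v_zero) / spec$rate_max
  pmin(pmax(v, spec$v_min), spec$v_max)
}

#' @rdname rate_to_voltage
#' @export
voltage_to_rate <- function(voltage, spec = gyro_spec()) {
  validate_gyro_spec(spec)
  v <- pmin(pmax(voltage, spec$v_min), spec$v_max)
  (v - spec$v_zero) * spec$rate_max / (spec$v_max - spec$v_zero)
}

#' Uniform mid-tread A/D quantization
#'
#' Quantizes a (clamped) voltage over the converter's full-scale range using
#' `2^adc_bits` uniformly spaced codes; half-way values round up. Returns the
#' reconstructed voltage of the nearest code, or the integer code itself.
#'
#' @inheritParams rate_to_voltage
#' @param codes If `TRUE`, return integer codes in
#'   `0 .. 2^adc_bits - 1` instead of reconstructed voltages.
#' @return Numeric vector of reconstructed voltages (V), or integer codes.
#' @examples
#' quantize_adc(2.5)               # 2.5098 V (code 128 of 0..255 over 0-5 V)
#' quantize_adc(2.5, codes = TRUE) # 128
#' @export
quantize_adc <- function(voltage, spec = gyro_spec(), codes = FALSE) {
  validate_gyro_spec(spec)
  lo <- spec$adc_range[1]
  hi <- spec$adc_range[2]
  n_codes <- 2^spec$adc_bits
  step <- (hi - lo) / (n_codes - 1)
  v <- pmin(pmax(voltage, lo), hi)
  # floor(x + 0.5) rounds half-way values up (round() would round half to even)
  code <- pmin(floor((v - lo) / step + 0.5), n_codes - 1)
  if (codes) return(as.integer(code))
  lo + code * step
}

#' Decimate a signal by keeping every k-th sample
#'
#' Plain decimation starting at the first sample; no anti-alias filtering is
#' applied (the simulated motion templates are band-limited far below the
#' decimated Nyquist frequency).
#'
#' @param x Numeric vector.
#' @param factor Integer decimation factor (>= 1).
#' @return Numeric vector of length `ceiling(length(x) / factor)`.
#' @examples
#' downsample_signal(1:40, 20) # c(1, 21)
#' @export
downsample_signal <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    abort("`factor` must be an integer >= 1.")
  }
  x[seq(1L, length(x), by = factor)]
}
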