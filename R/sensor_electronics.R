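#' Detector board geometry
#'
#' Sensors P1, P2, P3 lie along the tube axis at -10, 0, +10 mm; P4 and
#' P5 sit beside P2 with a 3.5 mm perpendicular offset and monitor tube
#' rotation.  Each phototransistor collects light over a small aperture
#' around its position.
#'
#' @param axial_positions P1..P3 axial coordinates (mm).
#' @param lateral_offsets P4/P5 perpendicular offsets (mm).
#' @param aperture Collection half-width (mm).
#' @param p45_attenuation In planar-2D mode P4/P5 cannot be sampled at
#'   their true perpendicular offsets; they are modeled as the P2 channel
#'   scaled by this factor (their peaks are lower than P2's).
#' @return A `sensor_geometry` list.
#' @export
sensor_geometry <- function(axial_positions = c(-10, 0, 10),
                            lateral_offsets = c(-3.5, 3.5),
                            aperture = 0.5, p45_attenuation = 0.8) {
  stopifnot(length(axial_positions) == 3, length(lateral_offsets) == 2,
            aperture > 0, p45_attenuation > 0)
  structure(list(axial_positions = axial_positions,
                 lateral_offsets = lateral_offsets,
                 aperture = aperture,
                 p45_attenuation = p45_attenuation),
            class = "sensor_geometry")
}

#' Electronics of the phototransistor chain
#'
#' Common-collector phototransistors on a +5 V rail with 430 k-ohm
#' emitter resistors setting the gain, an RC low-pass (200 k-ohm, 82 nF,
#' cutoff 9.7 Hz) on each output, and a DAQ sampling at 250 Hz with
#' 14-bit resolution.
#'
#' @param supply_voltage Rail voltage (V).
#' @param emitter_resistance Emitter resistor (ohm).
#' @param filter_resistance,filter_capacitance RC filter values (ohm, F).
#' @param sampling_rate DAQ rate (Hz).
#' @param adc_bits ADC resolution (bits).
#' @param responsivity Per-sensor gain, volts per unit intensity
#'   (length 5).
#' @return An `electronics_spec` list.
#' @export
electronics_spec <- function(supply_voltage = 5, emitter_resistance = 430e3,
                             filter_resistance = 200e3, filter_capacitance = 82e-9,
                             sampling_rate = 250, adc_bits = 14,
                             responsivity = rep(1, 5)) {
  stopifnot(supply_voltage > 0, emitter_resistance > 0, filter_resistance > 0,
            filter_capacitance > 0, sampling_rate > 0, adc_bits >= 1,
            length(responsivity) == 5, all(responsivity > 0))
  structure(list(supply_voltage = supply_voltage,
                 emitter_resistance = emitter_resistance,
                 filter_resistance = filter_resistance,
                 filter_capacitance = filter_capacitance,
                 sampling_rate = sampling_rate,
                 adc_bits = as.integer(adc_bits),
                 responsivity = responsivity),
            class = "electronics_spec")
}

#' Optical intensity collected by each sensor
#'
#' Sensor i integrates the skin exitance over
#' \[x_i - d - a, x_i - d + a\] where x_i is the sensor coordinate, d the
#' tube displacement (positive = tube pushed inward = light spot moving
#' toward P3) and a the aperture half-width.  P4/P5 share P2's axial
#' position; in planar-2D mode they are an attenuated copy of the P2
#' channel, while a 3D exitance map is sampled at their true
#' perpendicular offsets.
#'
#' @param profile An `exitance_profile`.
#' @param geometry A [sensor_geometry()].
#' @param displacement Tube displacement d (mm).
#' @return Numeric length-5 vector of intensities (P1..P5).
#' @export
sensor_intensities <- function(profile, geometry, displacement) {
  stopifnot(inherits(profile, "exitance_profile"))
  a <- geometry$aperture
  sample1d <- function(center) {
    xs <- seq(center - a, center + a, length.out = 7L)
    rng <- range(profile$bin_centers)
    if (any(xs < rng[1] | xs > rng[2])) {
      stop("sensor aperture falls outside the simulated domain", call. = FALSE)
    }
    mean(approx(profile$bin_centers, profile$intensity, xout = xs)$y)
  }
  axial <- geometry$axial_positions
  if (!is.null(profile$y_map)) {
    sample2d <- function(xc, yoff) {
      # pool a short y-strip around the sensor for photon statistics
      js <- which(abs(profile$y_centers - yoff) <= 1.25)
      if (!length(js)) js <- which.min(abs(profile$y_centers - yoff))
      col <- rowMeans(profile$y_map[, js, drop = FALSE])
      xs <- seq(xc - a, xc + a, length.out = 7L)
      mean(approx(profile$bin_centers, col, xout = xs, rule = 1)$y)
    }
    # all five sensors on the same per-bin scale from the 2D map
    I123 <- vapply(axial, function(x) sample2d(x - displacement, 0),
                   numeric(1))
    I45 <- vapply(geometry$lateral_offsets, function(yo) {
      sample2d(axial[2] - displacement, yo)
    }, numeric(1))
  } else {
    I123 <- vapply(axial, function(x) sample1d(x - displacement), numeric(1))
    I45 <- rep(I123[2] * geometry$p45_attenuation, 2)
  }
  c(I123, I45)
}

#' Convert optical intensity to an emitter voltage
#'
#' Linear response below the supply rail, hard-clamped at the rail:
#' V = min(supply, responsivity_i * intensity).
#'
#' @param intensity Non-negative intensity (vectorized).
#' @param spec An [electronics_spec()].
#' @param sensor_index Which sensor's responsivity to use (1..5).
#' @return Voltage(s) in volts.
#' @export
intensity_to_voltage <- function(intensity, spec, sensor_index = 1L) {
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  pmin(spec$supply_voltage, spec$responsivity[sensor_index] * intensity)
}

#' RC low-pass cutoff frequency
#'
#' @param resistance Resistance (ohm), positive.
#' @param capacitance Capacitance (F), positive.
#' @return Cutoff frequency 1/(2*pi*R*C) in Hz.
#' @export
#' @examples
#' rc_cutoff_frequency(200e3, 82e-9) # 9.7 Hz
rc_cutoff_frequency <- function(resistance, capacitance) {
  if (resistance <= 0 || capacitance <= 0) {
    stop("resistance and capacitance must be positive", call. = FALSE)
  }
  1 / (2 * pi * resistance * capacitance)
}

#' Apply the RC low-pass filter to a voltage series
#'
#' Discrete single-pole filter matching the analog RC at the given
#' sampling rate (pole exp(-2*pi*fc/fs)), with exact unit DC gain.
#' Initial state is the first sample of each channel.
#'
#' @param series A data frame with columns `vp1`..`vp5` (a voltage
#'   series), or a numeric vector.
#' @param cutoff Cutoff frequency (Hz), below Nyquist.
#' @param sampling_rate Sampling rate (Hz).
#' @return The filtered series, same shape as the input.
#' @export
apply_lowpass <- function(series, cutoff, sampling_rate = 250) {
  if (cutoff >= sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  a <- exp(-2 * pi * cutoff / sampling_rate)
  lp1 <- function(x) {
    as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                             init = x[1]))
  }
  if (is.numeric(series)) return(lp1(series))
  cols <- grep("^vp[1-5]$", names(series), value = TRUE)
  for (cl in cols) series[[cl]] <- lp1(series[[cl]])
  series
}

#' Add measurement noise and ADC quantization
#'
#' Adds Gaussian noise (additive volts and/or multiplicative fraction),
#' clamps to the supply rails and rounds to the nearest of 2^adc_bits
#' uniform levels spanning \[0, supply\] (half-away-from-zero on the
#' level index).  Seeded and reproducible.
#'
#' @param series Voltage series data frame (columns `vp1`..`vp5`) or a
#'   numeric vector.
#' @param spec An [electronics_spec()].
#' @param noise_sd Additive noise standard deviation (V), >= 0.
#' @param multiplicative_sd Fractional multiplicative noise sd, >= 0.
#' @param seed Optional integer seed.
#' @return The noisy, quantized series.
#' @export
quantize_and_noise <- function(series, spec, noise_sd = 0,
                               multiplicative_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, multiplicative_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  lsb <- spec$supply_voltage / (2^spec$adc_bits - 1)
  q1 <- function(x) {
    if (multiplicative_sd > 0) x <- x * (1 + rnorm(length(x), 0, multiplicative_sd))
    if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
    x <- pmin(spec$supply_voltage, pmax(0, x))
    floor(x / lsb + 0.5) * lsb
  }
  if (is.numeric(series)) return(q1(series))
  cols <- grep("^vp[1-5]$", names(series), value = TRUE)
  for (cl in cols) series[[cl]] <- q1(series[[cl]])
  series
}
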