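#' Parametric light-spot model for session synthesis
#'
#' The generator can drive the sensors either from a Monte Carlo
#' exitance profile (`shape = "mc_profile"`) or from a closed-form
#' pseudo-Gaussian spot (`shape = "pseudo_gaussian"`), which is fast
#' enough for test suites.  The pseudo-Gaussian emulates the qualitative
#' features of live measurements: per-sensor gain heterogeneity, broader
#' curves than the simulation predicts, off-axis attenuation of the
#' rotation sensors, and peaks not exactly centred on the nominal
#' positions.
#'
#' @param shape `"pseudo_gaussian"` or `"mc_profile"`.
#' @param width_sigma Gaussian width sigma (mm).  The default 7 mm puts
#'   the half-intensity half-width at `7*sqrt(2*log(2))` = 8.2 mm,
#'   slightly broader than the simulated 7.5 mm, as live tissue curves
#'   are.
#' @param peak_intensity Peak intensity in sensor units (default 3, i.e.
#'   ~3 V peaks at unit responsivity, comfortably below the 5 V rail).
#' @param per_sensor_gain Five positive gain factors (default P4/P5 at
#'   0.8: their peaks are lower).
#' @param broadening_factor Multiplies the width (>= 1).
#' @param peak_offsets Optional per-sensor peak position offsets (mm).
#' @return A `spot_profile_params` list.
#' @export
spot_profile_params <- function(shape = c("pseudo_gaussian", "mc_profile"),
                                width_sigma = 7, peak_intensity = 3,
                                per_sensor_gain = c(1, 1, 1, 0.8, 0.8),
                                broadening_factor = 1,
                                peak_offsets = rep(0, 5)) {
  shape <- match.arg(shape)
  stopifnot(width_sigma > 0, peak_intensity > 0,
            length(per_sensor_gain) == 5, all(per_sensor_gain > 0),
            broadening_factor >= 1, length(peak_offsets) == 5)
  structure(list(shape = shape, width_sigma = width_sigma,
                 peak_intensity = peak_intensity,
                 per_sensor_gain = per_sensor_gain,
                 broadening_factor = broadening_factor,
                 peak_offsets = peak_offsets),
            class = "spot_profile_params")
}

#' Motion protocol of a monitoring session
#'
#' One cycle is a back-and-forth sweep over the full range in uniform
#' steps, dwelling at each position; the defaults mirror the animal
#' protocol: +/-15 mm range, 1 mm steps, 5 cycles, with the tube
#' nominally at 0 rotation (the rotation schedule is used for dedicated
#' rotation measurements).
#'
#' @param range Half-range (mm), > 0.
#' @param step Step size (mm), > 0.
#' @param n_cycles Number of full cycles, >= 1.
#' @param dwell Dwell time per step (s).
#' @param rotation_schedule Rotation angles measured (degrees).
#' @param seed Integer seed.
#' @return A `motion_protocol` list.
#' @export
motion_protocol <- function(range = 15, step = 1, n_cycles = 5, dwell = 0.5,
                            rotation_schedule = c(0, 40, -40), seed = 1L) {
  stopifnot(range > 0, step > 0, n_cycles >= 1, dwell > 0)
  structure(list(range = range, step = step, n_cycles = n_cycles,
                 dwell = dwell, rotation_schedule = rotation_schedule,
                 seed = as.integer(seed)),
            class = "motion_protocol")
}

#' Noise model of a synthetic session
#'
#' `"linear_stage"` mode models stable positioning; `"manual"` mode adds
#' step jitter (the reference sensor records the jittered position, so
#' the truth column carries it) and a per-dwell per-sensor fractional
#' coupling wobble emulating tilt and hand tremor, which perturbs the
#' optics without moving the tube axially and is therefore invisible to
#' the reference sensor.  Magnitudes are synthetic placeholders for
#' sensitivity studies, not device characterizations.
#'
#' @param mode `"linear_stage"` or `"manual"`.
#' @param voltage_sd Additive voltage noise sd (V).
#' @param multiplicative_sd Fractional multiplicative voltage noise sd.
#' @param gain_drift_sd Fractional per-cycle gain drift sd.
#' @param step_jitter_sd Step jitter sd (mm); manual mode requires > 0.
#' @param coupling_sd Per-dwell fractional coupling wobble sd (manual
#'   mode only).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(mode = c("linear_stage", "manual"), voltage_sd = 0.01,
                       multiplicative_sd = 0, gain_drift_sd = 0,
                       step_jitter_sd = 0.3, coupling_sd = 0.02) {
  mode <- match.arg(mode)
  stopifnot(voltage_sd >= 0, multiplicative_sd >= 0, gain_drift_sd >= 0,
            step_jitter_sd >= 0, coupling_sd >= 0)
  if (mode == "manual" && step_jitter_sd <= 0) {
    stop("manual mode requires step_jitter_sd > 0", call. = FALSE)
  }
  structure(list(mode = mode, voltage_sd = voltage_sd,
                 multiplicative_sd = multiplicative_sd,
                 gain_drift_sd = gain_drift_sd,
                 step_jitter_sd = step_jitter_sd,
                 coupling_sd = coupling_sd),
            class = "noise_spec")
}

#' Forward voltage/ratio curves versus displacement
#'
#' Builds the noiseless per-sensor voltage curves over a displacement
#' grid, plus the corresponding r12/r32 ratio curves.  In
#' pseudo-Gaussian mode sensor i at axial position x_i (perpendicular
#' offset y_i) reads
#' \deqn{V_i(d) = g_i A \exp(-((x_i - d - o_i)^2 + y_i^2) / (2 s^2))}
#' with s = width_sigma * broadening_factor.  In `mc_profile` mode the
#' curves are sampled from a Monte Carlo exitance profile.
#'
#' @param params A [spot_profile_params()].
#' @param geometry A [sensor_geometry()].
#' @param stack A `tissue_stack` (required for `mc_profile` mode).
#' @param grid Displacement grid (mm).
#' @param source,smoothing_window MC-mode options.
#' @param ... Further arguments to [run_mc()].
#' @return A `forward_curves` object: list with `d` (grid), `V`
#'   (length(d) x 5 voltage matrix), `r12`, `r32`, `params`, `geometry`.
#' @export
make_forward_curves <- function(params, geometry = sensor_geometry(),
                                stack = NULL, grid = seq(-20, 20, by = 0.25),
                                source = NULL, smoothing_window = 6L, ...) {
  stopifnot(inherits(params, "spot_profile_params"))
  xs <- c(geometry$axial_positions, rep(geometry$axial_positions[2], 2))
  ys <- c(0, 0, 0, geometry$lateral_offsets)
  if (params$shape == "pseudo_gaussian") {
    s <- params$width_sigma * params$broadening_factor
    V <- sapply(1:5, function(i) {
      params$per_sensor_gain[i] * params$peak_intensity *
        exp(-((xs[i] - grid - params$peak_offsets[i])^2 + ys[i]^2) / (2 * s^2))
    })
  } else {
    if (is.null(stack)) stop("mc_profile mode requires a tissue stack", call. = FALSE)
    if (is.null(source)) source <- source_spec()
    prof <- run_mc(stack, source, ...)$profile
    prof <- smooth_profile(prof, smoothing_window)
    V <- t(vapply(grid, function(d) {
      Iv <- sensor_intensities(prof, geometry, d)
      params$per_sensor_gain * params$peak_intensity * Iv / max(prof$intensity)
    }, numeric(5)))
  }
  colnames(V) <- paste0("vp", 1:5)
  structure(list(d = grid, V = V,
                 r12 = V[, 1] / V[, 2], r32 = V[, 3] / V[, 2],
                 params = params, geometry = geometry),
            class = "forward_curves")
}

#' Evaluate forward curves at arbitrary displacements
#'
#' @param curves A `forward_curves` object.
#' @param d Displacements (mm), inside the curve grid.
#' @return A length(d) x 5 voltage matrix.
#' @export
curve_voltages <- function(curves, d) {
  rng <- range(curves$d)
  if (any(d < rng[1] | d > rng[2])) {
    stop("displacement outside the forward-curve domain", call. = FALSE)
  }
  out <- sapply(1:5, function(i) approx(curves$d, curves$V[, i], xout = d)$y)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(d))
  colnames(out) <- paste0("vp", 1:5)
  out
}

#' Generate a synthetic monitoring session
#'
#' Emits a seeded voltage log at the DAQ rate covering `n_cycles`
#' back-and-forth sweeps with dwell plateaus, applying the electronics
#' chain in order: rail saturation, RC low-pass, additive/multiplicative
#' noise and ADC quantization.  The per-frame truth column `ref_mm`
#' records what the reference position sensor would read (the jittered
#' position in manual mode).
#'
#' @param curves A `forward_curves` object.
#' @param protocol A [motion_protocol()].
#' @param noise A [noise_spec()].
#' @param electronics An [electronics_spec()].
#' @param seed Integer seed; defaults to the protocol seed.
#' @return A `session` list: `series` (data frame `time`, `vp1`..`vp5`,
#'   `ref_mm`, `cycle`), and the generating `protocol`, `noise`,
#'   `electronics`, `seed`.
#' @export
generate_session <- function(curves, protocol = motion_protocol(),
                             noise = noise_spec(), electronics = electronics_spec(),
                             seed = protocol$seed) {
  r <- protocol$range; st <- protocol$step
  if (r > max(abs(curves$d))) {
    stop("protocol range exceeds the forward-curve domain", call. = FALSE)
  }
  up <- seq(-r, r, by = st)
  cyc <- c(up, rev(up[-1])[-1]) # -r..+r, then +r-st down to -r+st
  set.seed(seed)
  fs <- electronics$sampling_rate
  npf <- max(1L, round(protocol$dwell * fs))
  gains <- rep(1, 5)
  pos <- numeric(0); cyid <- integer(0); volts <- NULL
  for (ic in seq_len(protocol$n_cycles)) {
    if (noise$gain_drift_sd > 0) {
      gains <- gains * (1 + rnorm(5, 0, noise$gain_drift_sd))
    }
    for (p in cyc) {
      actual <- p
      if (noise$mode == "manual" && noise$step_jitter_sd > 0) {
        actual <- p + rnorm(1, 0, noise$step_jitter_sd)
        actual <- min(max(actual, min(curves$d)), max(curves$d))
      }
      v <- as.numeric(curve_voltages(curves, actual)) * gains
      if (noise$mode == "manual" && noise$coupling_sd > 0) {
        v <- v * (1 + rnorm(5, 0, noise$coupling_sd))
      }
      v <- pmin(electronics$supply_voltage, pmax(0, v))
      volts <- rbind(volts, matrix(v, nrow = npf, ncol = 5, byrow = TRUE))
      pos <- c(pos, rep(actual, npf))
      cyid <- c(cyid, rep(ic, npf))
    }
  }
  n <- length(pos)
  series <- data.frame(time = (seq_len(n) - 1) / fs,
                       vp1 = volts[, 1], vp2 = volts[, 2], vp3 = volts[, 3],
                       vp4 = volts[, 4], vp5 = volts[, 5],
                       ref_mm = pos, cycle = cyid)
  fc <- rc_cutoff_frequency(electronics$filter_resistance,
                            electronics$filter_capacitance)
  series <- apply_lowpass(series, fc, fs)
  series <- quantize_and_noise(series, electronics, noise$voltage_sd,
                               noise$multiplicative_sd)
  structure(list(series = series, protocol = protocol, noise = noise,
                 electronics = electronics, seed = seed),
            class = "session")
}

#' Generate a calibration log
#'
#' Five dwell segments at -10, -5, 0, +5, +10 mm, tagged with a `cal_mm`
#' column for the calibration stage.
#'
#' @param curves A `forward_curves` object.
#' @param electronics An [electronics_spec()].
#' @param dwell Dwell per calibration position (s).  The 2 s default
#'   leaves the RC filter transient far below numerical tolerance in
#'   the trimmed averaging window.
#' @param noise A [noise_spec()] or `NULL` for a noiseless log.
#' @param seed Integer seed.
#' @return A `session` list whose series carries `cal_mm`.
#' @export
generate_calibration_log <- function(curves, electronics = electronics_spec(),
                                     dwell = 2, noise = NULL, seed = 1L) {
  dpos <- c(-10, -5, 0, 5, 10)
  if (max(abs(dpos)) > max(abs(curves$d))) {
    stop("calibration positions exceed the forward-curve domain", call. = FALSE)
  }
  set.seed(seed)
  fs <- electronics$sampling_rate
  npf <- max(2L, round(dwell * fs))
  volts <- NULL; pos <- numeric(0)
  for (p in dpos) {
    v <- pmin(electronics$supply_voltage,
              pmax(0, as.numeric(curve_voltages(curves, p))))
    volts <- rbind(volts, matrix(v, nrow = npf, ncol = 5, byrow = TRUE))
    pos <- c(pos, rep(p, npf))
  }
  n <- length(pos)
  series <- data.frame(time = (seq_len(n) - 1) / fs,
                       vp1 = volts[, 1], vp2 = volts[, 2], vp3 = volts[, 3],
                       vp4 = volts[, 4], vp5 = volts[, 5],
                       ref_mm = pos, cal_mm = pos)
  fc <- rc_cutoff_frequency(electronics$filter_resistance,
                            electronics$filter_capacitance)
  series <- apply_lowpass(series, fc, fs)
  if (!is.null(noise)) {
    series <- quantize_and_noise(series, electronics, noise$voltage_sd,
                                 noise$multiplicative_sd)
  }
  structure(list(series = series, protocol = NULL, noise = noise,
                 electronics = electronics, seed = seed),
            class = "session")
}

#' Extract a calibration set from a tagged log
#'
#' Averages per-frame ratios over each tagged dwell, discarding the
#' leading fraction of each dwell (filter transient).
#'
#' @param log A `session` (or its series data frame) with a `cal_mm`
#'   column.
#' @param floor VP2 signal floor (V).
#' @param trim Leading fraction of each dwell to discard.
#' @return A [calibration_set()], plus attribute `p45_baselines`
#'   (calibration-time VP4/VP2 and VP5/VP2 at d = 0) for the rotation
#'   alert.
#' @export
calibration_set_from_log <- function(log, floor = 0.02, trim = 0.2) {
  series <- if (inherits(log, "session")) log$series else log
  if (is.null(series$cal_mm)) {
    stop("log has no cal_mm dwell tags; not a calibration log", call. = FALSE)
  }
  dwells <- unique(series$cal_mm)
  rows <- lapply(dwells, function(p) {
    seg <- series[series$cal_mm == p, ]
    keep <- seq(from = base::floor(nrow(seg) * trim) + 1, to = nrow(seg))
    seg <- seg[keep, , drop = FALSE]
    if (any(seg$vp2 <= floor)) {
      stop("low-signal frames inside the ", p, " mm calibration dwell",
           call. = FALSE)
    }
    data.frame(displacement = p,
               r12 = mean(seg$vp1 / seg$vp2),
               r32 = mean(seg$vp3 / seg$vp2),
               r42 = mean(seg$vp4 / seg$vp2),
               r52 = mean(seg$vp5 / seg$vp2))
  })
  tab <- do.call(rbind, rows)
  cal <- calibration_set(tab$displacement, tab$r12, tab$r32)
  attr(cal, "p45_baselines") <- c(tab$r42[tab$displacement == 0],
                                  tab$r52[tab$displacement == 0])
  cal
}
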