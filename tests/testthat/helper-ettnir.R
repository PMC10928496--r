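# Shared fixtures, all built in code.

# Gaussian exitance profile on a fine grid (analytic reference spot).
gaussian_profile <- function(sigma = 5, dx = 0.1, halfwidth = 40, peak = 1) {
  x <- seq(-halfwidth, halfwidth, by = dx)
  exitance_profile(x, peak * exp(-x^2 / (2 * sigma^2)), bin_width = dx)
}

# Calibration set taken straight from noiseless forward curves.
curves_calibration_set <- function(curves) {
  d <- c(-10, -5, 0, 5, 10)
  V <- curve_voltages(curves, d)
  calibration_set(d, V[, 1] / V[, 2], V[, 3] / V[, 2])
}

# Default pseudo-Gaussian curves with symmetric unit gains.
symmetric_curves <- function(...) {
  make_forward_curves(spot_profile_params(per_sensor_gain = rep(1, 5), ...),
                      sensor_geometry())
}

# One modest default-stack 2D run shared by the transport tests.
shared_mc_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_mc(default_tissue_stack(),
                       source_spec(n_packets = 3e5, seed = 42))
    }
    cache
  }
})
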