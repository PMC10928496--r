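test_that("voltage ratios are computed with a low-signal guard", {
  expect_equal(compute_ratios(c(1, 1, 1, 0, 0)), list(r12 = 1, r32 = 1))
  expect_equal(compute_ratios(list(vp1 = 3, vp2 = 2, vp3 = 1)),
               list(r12 = 1.5, r32 = 0.5))
  expect_error(compute_ratios(list(vp1 = 1, vp2 = 0.001, vp3 = 1)),
               "low-signal")
})

test_that("calibration sets require exactly the five displacements", {
  expect_error(calibration_set(c(-10, -5, 0, 5), 1:4, 1:4), "exactly")
  expect_error(calibration_set(c(-10, -5, 0, 5, 5), rep(1, 5), rep(1, 5)),
               "exactly")
  expect_error(calibration_set(c(-10, -5, 0, 5, 10), c(1, 1, NA, 1, 1),
                               rep(1, 5)), "non-finite")
  cal <- calibration_set(c(10, 5, 0, -5, -10), 5:1, 1:5)
  expect_equal(cal$displacement, c(-10, -5, 0, 5, 10)) # sorted
})

test_that("each branch interpolates its three nodes exactly", {
  cal <- calibration_set(c(-10, -5, 0, 5, 10),
                         r12 = c(2.0, 1.4, 1.0, 0.7, 0.5),
                         r32 = c(0.5, 0.7, 1.0, 1.5, 2.3))
  m <- fit_calibration(cal)
  f <- function(cf, d) cf[1] + cf[2] * d + cf[3] * d^2
  expect_equal(f(m$f12_high, c(-10, -5, 0)), c(2.0, 1.4, 1.0), tolerance = 1e-9)
  expect_equal(f(m$f32_low, c(-10, -5, 0)), c(0.5, 0.7, 1.0), tolerance = 1e-9)
  expect_equal(f(m$f32_high, c(0, 5, 10)), c(1.0, 1.5, 2.3), tolerance = 1e-9)
  expect_equal(f(m$f12_low, c(0, 5, 10)), c(1.0, 0.7, 0.5), tolerance = 1e-9)
  expect_equal(m$r12_zero, 1.0)
  expect_true(all(m$monotone))
})

test_that("nodes lying on an exact quadratic recover its coefficients", {
  d <- c(-10, -5, 0)
  r <- 1 + 0.01 * d + 0.002 * d^2
  cal <- calibration_set(c(-10, -5, 0, 5, 10),
                         r12 = c(r, 0.9, 0.8), r32 = c(0.8, 0.9, 1, 1.1, 1.2))
  # (this synthetic r12 branch has its vertex at -2.5 mm, so the fit
  #  legitimately warns about monotonicity; only recovery is under test)
  m <- suppressWarnings(fit_calibration(cal))
  expect_equal(m$f12_high, c(1, 0.01, 0.002), tolerance = 1e-10)
})

test_that("a vertex inside the half-range raises the monotonicity flag", {
  # independent check of the vertex location via least squares
  d <- c(0, 5, 10); r <- c(1, 1.2, 1.1)
  cf <- unname(coef(lm(r ~ d + I(d^2))))
  vertex <- -cf[2] / (2 * cf[3])
  expect_equal(vertex, 35 / 6, tolerance = 1e-9)
  expect_true(vertex > 0 && vertex < 10)

  cal <- calibration_set(c(-10, -5, 0, 5, 10),
                         r12 = c(2, 1.4, 1, 1.2, 1.1),
                         r32 = c(0.5, 0.7, 1, 1.5, 2.3))
  expect_warning(m <- fit_calibration(cal), "f12_low")
  expect_false(m$monotone[["f12_low"]])
  expect_true(m$monotone[["f32_high"]])
})

test_that("direction classification follows the baseline-ratio rule", {
  cal <- calibration_set(c(-10, -5, 0, 5, 10),
                         r12 = c(2.0, 1.4, 1.0, 0.7, 0.5),
                         r32 = c(0.5, 0.7, 1.0, 1.5, 2.3))
  m <- fit_calibration(cal)
  expect_equal(classify_direction(list(r12 = 1.2), m), "negative")
  expect_equal(classify_direction(list(r12 = 0.8), m), "positive")
  expect_equal(classify_direction(list(r12 = 1.0), m), "zero")
  # deadband widens the zero region
  expect_equal(classify_direction(list(r12 = 1.05), m, deadband = 0.1), "zero")
})

test_that("branch inversion recovers nodes, handles linear fits and clamps", {
  cal <- calibration_set(c(-10, -5, 0, 5, 10),
                         r12 = c(2.0, 1.4, 1.0, 0.7, 0.5),
                         r32 = c(0.5, 0.7, 1.0, 1.5, 2.2))
  m <- fit_calibration(cal)
  inv <- invert_branch(m$f12_high, 1.4, c(-10, 0))
  expect_equal(inv$d, -5, tolerance = 1e-9)
  expect_false(inv$clamped)

  # zero-curvature branch: plain linear inversion
  lin <- invert_branch(c(1, -0.05, 0), 0.75, c(0, 10))
  expect_equal(lin$d, 5, tolerance = 1e-12)

  # evaluating the (0,1.0), (5,1.5), (10,2.2) interpolant at its end node
  inv10 <- invert_branch(m$f32_high, 2.2, c(0, 10))
  expect_equal(inv10$d, 10, tolerance = 1e-9)

  # ratio beyond the calibrated range clamps with a flag
  over <- invert_branch(m$f32_high, 3.5, c(0, 10))
  expect_true(over$clamped)
  expect_equal(over$d, 10)
  under <- invert_branch(m$f12_high, 0.2, c(-10, 0))
  expect_true(under$clamped)

  expect_error(invert_branch(c(1, 0, 0), 0.75, c(0, 10)), "degenerate")
})

test_that("estimates recover all five calibration nodes and fuse exactly", {
  curves <- symmetric_curves()
  cal <- curves_calibration_set(curves)
  m <- fit_calibration(cal)
  for (d0 in c(-10, -5, 0, 5, 10)) {
    i <- which(cal$displacement == d0)
    est <- estimate_displacement(list(r12 = cal$r12[i], r32 = cal$r32[i]), m)
    expect_lt(abs(est$d_final - d0), 1e-6)
    # weighted-fusion identity, exact
    expect_identical(est$d_final,
                     m$weight_w * est$d_high + (1 - m$weight_w) * est$d_low)
  }
  base <- estimate_displacement(list(r12 = m$r12_zero, r32 = m$r32_zero), m)
  expect_equal(base$d_final, 0)
  expect_equal(base$direction, "zero")
})

test_that("estimates are invariant to a common gain factor below saturation", {
  curves <- symmetric_curves()
  m <- fit_calibration(curves_calibration_set(curves))
  V <- curve_voltages(curves, -6.3)
  e1 <- estimate_displacement(list(r12 = V[1] / V[2], r32 = V[3] / V[2]), m)
  k <- 0.37
  e2 <- estimate_displacement(list(r12 = k * V[1] / (k * V[2]),
                                   r32 = k * V[3] / (k * V[2])), m)
  expect_equal(e1$d_final, e2$d_final, tolerance = 1e-12)
})

test_that("rotation alert flags baseline deviations beyond the threshold", {
  base <- c(0.8, 0.8)
  frame <- list(vp2 = 2, vp4 = 1.6, vp5 = 1.6) # exactly at baseline
  expect_false(rotation_alert(frame, base)$flagged)
  hot <- list(vp2 = 2, vp4 = 2.4, vp5 = 1.6)   # VP4/VP2 = 1.5 x baseline
  expect_true(rotation_alert(hot, base, threshold = 0.30)$flagged)
  expect_true(rotation_alert(list(vp2 = 2, vp4 = 1.61, vp5 = 1.6),
                             base, threshold = 0)$flagged)
  expect_error(rotation_alert(list(vp2 = 0.001, vp4 = 1, vp5 = 1), base),
               "low-signal")
})

test_that("series tracking is monotone, constant on plateaus, and isolates dropouts", {
  curves <- symmetric_curves()
  m <- fit_calibration(curves_calibration_set(curves))

  # constant frames at the +5 mm calibration values
  V5 <- curve_voltages(curves, 5)
  ser <- data.frame(vp1 = rep(V5[1], 10), vp2 = V5[2], vp3 = V5[3],
                    vp4 = V5[4], vp5 = V5[5])
  out <- track_series(ser, m)
  expect_true(all(abs(out$d_final - 5) < 1e-6))

  # noiseless sweep: the estimate stream is non-decreasing in d
  dgrid <- seq(-10, 10, by = 1)
  Vs <- curve_voltages(curves, dgrid)
  sweep <- as.data.frame(Vs)
  est <- track_series(sweep, m)
  expect_true(all(diff(est$d_final) >= -1e-9))
  # direction is classified correctly for |d| >= 1 on the noiseless sweep
  expect_true(all(est$direction[dgrid <= -1] == "negative"))
  expect_true(all(est$direction[dgrid >= 1] == "positive"))

  # one VP2 dropout yields one flagged missing estimate
  drop <- sweep
  drop$vp2[7] <- 0.001
  est2 <- track_series(drop, m)
  expect_true(is.na(est2$d_final[7]))
  expect_equal(est2$reason[7], "low_signal")
  expect_equal(est2$d_final[-7], est$d_final[-7])
})
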