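test_that("tissue stacks validate their layers and derive total thickness", {
  stack <- default_tissue_stack()
  expect_s3_class(stack, "tissue_stack")
  expect_equal(nrow(stack), 5)
  expect_equal(attr(stack, "total_thickness"), 16)

  one <- build_tissue_stack(data.frame(name = "slab", thickness_mm = 5,
                                       mu_a = 1, mu_s = 10, g = 0.5, n = 1.4))
  expect_equal(attr(one, "total_thickness"), 5)

  bad_g <- data.frame(name = "skin", thickness_mm = 0.5, mu_a = 1.8,
                      mu_s = 408, g = 1.2, n = 1.36)
  expect_error(build_tissue_stack(bad_g), "'g'")
  expect_error(tissue_layer("x", -1, 1, 1, 0.5, 1.4), "thickness")
  expect_error(tissue_layer("x", 1, 1, 1, 0.5, 0.9), "'n'")
  expect_error(build_tissue_stack(list()), "at least one layer")
})

test_that("Henyey-Greenstein sampling has the right support, limits and mean", {
  expect_equal(sample_hg_cosine(0, 0.5), 0)
  expect_equal(sample_hg_cosine(0, c(0, 1)), c(-1, 1))
  # forward-peaked limit
  expect_gt(sample_hg_cosine(0.9, 1 - 1e-12), 0.9999)

  set.seed(101)
  n <- 1e6
  for (g in c(0, 0.79, 0.9, 0.95)) {
    cth <- sample_hg_cosine(g, runif(n))
    expect_true(all(cth >= -1 & cth <= 1))
    se <- sd(cth) / sqrt(n)
    expect_lt(abs(mean(cth) - g), 3 * se + 1e-12)
  }
})

test_that("Fresnel interface covers matched, refracted and trapped rays", {
  m <- fresnel_interface(1.4, 1.4, 0.3)
  expect_equal(m$reflect_probability, 0)
  expect_equal(m$cos_refracted, 0.3)

  # beyond the critical angle of a 1.45 -> 1.40 step (cos_c ~ 0.26)
  tir <- fresnel_interface(1.45, 1.40, 0.1)
  expect_equal(tir$reflect_probability, 1)
  expect_true(is.na(tir$cos_refracted))

  # normal incidence air -> tissue: ((n2-n1)/(n2+n1))^2 = (0.4/2.4)^2
  nrm <- fresnel_interface(1.0, 1.4, 1.0)
  expect_equal(nrm$reflect_probability, (0.4 / 2.4)^2, tolerance = 1e-12)
  expect_equal(nrm$cos_refracted, 1.0)

  # reflectance rises monotonically toward grazing incidence
  ci <- seq(1, 0.05, by = -0.05)
  rr <- vapply(ci, function(c) fresnel_interface(1.0, 1.4, c)$reflect_probability,
               numeric(1))
  expect_true(all(diff(rr) >= 0))
})

test_that("profile smoothing is a centered partial-window moving average", {
  x <- seq(-10, 10, by = 0.5)
  const <- exitance_profile(x, rep(2, length(x)))
  expect_equal(smooth_profile(const, 1)$intensity, const$intensity)
  expect_equal(smooth_profile(const, 6)$intensity, const$intensity)

  imp <- rep(0, length(x)); imp[21] <- 3
  sm <- smooth_profile(exitance_profile(x, imp), 6)
  inner <- sm$intensity[17:23] # indices whose window contains the impulse
  expect_true(all(abs(inner[inner > 0] - 3 / 6) < 1e-12))
  expect_equal(sum(sm$intensity > 0), 6)
  expect_equal(sm$smoothing_window, 6L)

  expect_error(smooth_profile(const, length(x) + 1), "window")
})

test_that("half-intensity half-width matches closed-form shapes", {
  # triangle: peak 1 at 0, zero at +/-10 -> half-crossing at +/-5
  x <- seq(-15, 15, by = 0.25)
  tri <- exitance_profile(x, pmax(0, 1 - abs(x) / 10))
  expect_equal(half_intensity_halfwidth(tri), 5, tolerance = 1e-9)

  # Gaussian sigma = 5 -> sigma * sqrt(2 log 2)
  expect_equal(half_intensity_halfwidth(gaussian_profile(sigma = 5)),
               5 * sqrt(2 * log(2)), tolerance = 1e-3)

  # truncated domain with no crossing
  nar <- exitance_profile(seq(-1, 1, 0.1), exp(-seq(-1, 1, 0.1)^2 / 50))
  expect_error(half_intensity_halfwidth(nar))
})

test_that("transport conserves energy and reduces to Beer-Lambert", {
  # pure absorber, matched indices, pencil beam: exp(-mu_a * t)
  st <- build_tissue_stack(data.frame(name = "slab", thickness_mm = 5,
                                      mu_a = 2, mu_s = 0, g = 0, n = 1.4))
  np <- 1e5
  out <- run_mc(st, source_spec(angular_model = "pencil", n_packets = np,
                                seed = 7),
                n_outer = c(1.4, 1.4))
  p <- exp(-2 * 0.5) # mu_a in 1/cm, thickness 0.5 cm
  se <- sqrt(p * (1 - p) / np)
  expect_lt(abs(out$tally$skin_exitance_weight - p), 3 * se)

  for (res in list(out, shared_mc_run())) {
    ty <- res$tally
    total <- ty$absorbed_weight + ty$skin_exitance_weight +
      ty$lumen_reflectance_weight + ty$lateral_escape_weight
    expect_lt(abs(total - ty$launched_weight), 1e-3)
    expect_true(all(unlist(ty) >= 0))
  }
})

test_that("identical stack, source and seed reproduce bit-identical output", {
  st <- default_tissue_stack()
  a <- run_mc(st, source_spec(n_packets = 2e4, seed = 99))
  b <- run_mc(st, source_spec(n_packets = 2e4, seed = 99))
  expect_identical(a$profile$intensity, b$profile$intensity)
  expect_identical(unlist(a$tally), unlist(b$tally))
  c <- run_mc(st, source_spec(n_packets = 2e4, seed = 100))
  expect_false(identical(a$profile$intensity, c$profile$intensity))
})

test_that("default-stack skin profile is symmetric with monotone flanks", {
  res <- shared_mc_run()
  pr <- smooth_profile(res$profile, 6)
  x <- pr$bin_centers
  I <- pr$intensity
  np <- res$profile$n_packets
  # packet weights are <= 1, so Var(bin) <= I_bin / np
  se <- sqrt(pmax(I, 1e-12) / np)
  sel <- which(x > 0.4 & x < 12)
  mirror <- vapply(x[sel], function(xi) which.min(abs(x + xi)), integer(1))
  expect_true(all(abs(I[sel] - I[mirror]) <=
                    4 * sqrt(se[sel]^2 + se[mirror]^2) + 1e-12))

  # monotone decrease beyond 2 mm from the peak, up to MC noise
  ipk <- which.max(I)
  right <- which(x >= x[ipk] + 2 & x <= 20)
  drops <- diff(I[right])
  expect_true(all(drops <= 4 * sqrt(se[right[-1]]^2 + se[right[-length(right)]]^2)))
})

test_that("simulated ratio curves reproduce the branch asymmetry", {
  res <- shared_mc_run()
  pr <- smooth_profile(res$profile, 6)
  geo <- sensor_geometry()
  rc <- simulate_ratio_curves(NULL, NULL, geo, c(-10, -5, 0, 5, 10),
                              profile = pr)
  # mirror symmetry of the centered source: r12 = r32 at d = 0 (MC noise)
  expect_lt(abs(log(rc$r12[rc$d == 0] / rc$r32[rc$d == 0])), 0.25)
  # pulled-out tube (d < 0): spot near P1, so r12 dominates; reversed for d > 0
  expect_true(all(rc$r12[rc$d < 0] > rc$r32[rc$d < 0]))
  expect_true(all(rc$r12[rc$d > 0] < rc$r32[rc$d > 0]))
  # out-of-domain sensor position rejected
  expect_error(sensor_intensities(pr, geo, 45), "domain")
})

test_that("3D transport conserves energy and is insensitive to lobe tilt", {
  st <- default_tissue_stack()
  geo <- sensor_geometry()
  ds <- seq(-6, 6, by = 3)
  runs <- lapply(c(0, 40, -40), function(tilt) {
    res <- run_mc(st, source_spec(n_packets = 1.5e6, seed = 11 + tilt,
                                  tilt_angle = tilt), "slab3D",
                  strip_halfwidth = 4)
    ty <- res$tally
    total <- ty$absorbed_weight + ty$skin_exitance_weight +
      ty$lumen_reflectance_weight + ty$lateral_escape_weight
    expect_lt(abs(total - 1), 1e-3)
    res
  })
  curves <- lapply(runs, function(res) {
    # ratio curves from the smoothed wide-strip 1D profile (P1-P3 sit on
    # the axis; the strip integral maximizes photon statistics)
    p <- smooth_profile(res$profile, 6)
    strip <- exitance_profile(p$bin_centers, p$intensity, p$bin_width)
    simulate_ratio_curves(NULL, NULL, geo, ds, profile = strip)
  })
  # rotating the side-firing lobe by +/-40 deg leaves the working ratios
  # within an MC-noise band of the 0 deg curves
  for (k in 2:3) {
    expect_lt(max(abs(log(curves[[k]]$r12 / curves[[1]]$r12))), 0.35)
    expect_lt(max(abs(log(curves[[k]]$r32 / curves[[1]]$r32))), 0.35)
  }
  # P4/P5 read lower than P2 at their 3.5 mm offset
  I <- sensor_intensities(smooth_profile(runs[[1]]$profile, 6), geo, 0)
  expect_lt(I[4], I[2])
  expect_lt(I[5], I[2])
})

test_that("run_mc validates its inputs", {
  st <- default_tissue_stack()
  expect_error(run_mc(st, source_spec(), "flatland"))
  expect_warning(run_mc(st, source_spec(n_packets = 100, seed = 1)),
                 "noisy")
  expect_error(source_spec(tilt_angle = 120))
})
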