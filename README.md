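# ettnir

Simulation and estimation toolkit for **optical monitoring of
endotracheal tube (ETT) position**. An ETT that drifts along the trachea
can slip into a bronchus or out of the airway; `ettnir` models a
monitoring approach in which a side-firing optical fiber on the tube
illuminates the tracheal wall with 810 nm near-infrared light and five
phototransistors taped to the chest skin track the transmitted light
spot as the tube moves.

The package covers the whole computational chain:

* **Tissue optics** — a layered-slab Monte Carlo photon-transport kernel
  (C++/Rcpp): exponential step sampling against `mu_t`, partial
  absorption `mu_a/mu_t` per interaction, Henyey–Greenstein scattering,
  Fresnel handling at every index step, Russian roulette; planar-2D and
  full-3D modes; a default five-layer tracheal stack (mucosa, cartilage,
  adipose, muscle, skin; 16 mm total).
* **Sensor electronics** — board geometry (P1–P3 at −10/0/+10 mm along
  the tube, P4/P5 ±3.5 mm beside P2), linear-with-saturation
  phototransistor response, RC low-pass (200 kΩ × 82 nF → 9.7 Hz),
  250 Hz sampling, 14-bit quantization, seeded noise.
* **Calibration & estimation** — the core algorithm. Two ratios
  `r12 = VP1/VP2`, `r32 = VP3/VP2`; five-point calibration at −10, −5,
  0, +5, +10 mm; four exactly-interpolating quadratic branches
  (`f12_high`/`f32_low` on the negative half-range, `f32_high`/`f12_low`
  on the positive); direction from `r12(d)/r12(0)` vs 1; monotone branch
  inversion; weighted fusion
  `d_final = w*d_high + (1-w)*d_low` with `w = 0.95`; rotation alert
  from P4/P5.
* **Synthetic sessions** — seeded voltage logs emulating the bench/animal
  protocol (±15 mm sweeps, 1 mm steps, 5 cycles, manual vs linear-stage
  noise modes) so every stage is testable without hardware.
* **Agreement statistics** — OLS scatter regression, Bland–Altman with
  constant or regression-estimated bias and 1.96·SD limits of
  agreement, cycle-wise interpolation summaries.

## Worked example

```r
library(ettnir)

# Transport: where does the light exit the skin?
res <- run_mc(default_tissue_stack(),
              source_spec(n_packets = 2e6, seed = 1))
res$tally
#> Transport tally (fractions of 1 W launched)
#>   absorbed: 0.5269  skin exitance: 0.0032
#>   lumen reflectance: 0.4700  lateral escape: 0.0000
half_intensity_halfwidth(smooth_profile(res$profile, 6))
#> [1] 7.472414
```

About 0.3% of the launched power reaches the skin; the smoothed spot
falls to half its peak ≈7.5 mm to each side — wide enough to span the
10 mm sensor spacing, which is what makes the ratio method work.

```r
# Synthesize a monitored session, calibrate, track, and validate
curves <- make_forward_curves(spot_profile_params(), sensor_geometry())
cal    <- calibration_set_from_log(generate_calibration_log(curves))
model  <- fit_calibration(cal)                     # w = 0.95
ses    <- generate_session(curves, motion_protocol(n_cycles = 5, seed = 1),
                           noise_spec(mode = "linear_stage"))
est    <- track_series(ses$series, model)
ok     <- is.finite(est$d_final)
bland_altman(est$d_final[ok], est$ref_mm[ok], "regression")
#> Agreement report (n = 37500, bias model: regression)
#>   scatter OLS: slope 0.8481, intercept -0.0013 mm, R^2 0.9785
#>   bias: -0.0014 -0.1545 * mean (mm); LoA half-width 2.3077 mm
```

The slope below 1 and the LoA width come mostly from the ±10…±15 mm
tails, where ratios leave the calibrated range and estimates clamp at
±10 mm (flagged in `est$clamped`); inside the calibrated ±10 mm range
the estimator tracks the truth to well under a millimetre at these
noise levels. `run_pipeline()` wires these stages together and writes
logs, model, estimates and report with a reproducibility manifest; a
thin command-line surface over the same functions is installed at
`inst/cli/ettnir.R` (subcommands `simulate`, `synth`, `calibrate`,
`estimate`, `validate`).

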