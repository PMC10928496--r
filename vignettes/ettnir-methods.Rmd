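---
title: "Models and methods behind ettnir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ettnir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ettnir)
```

## The measurement problem

An endotracheal tube (ETT) that drifts along the trachea can end up in a
bronchus or slip out of the airway entirely; both are dangerous and
neither is visible from outside the patient. `ettnir` models an optical
monitoring approach: a side-firing fiber on the tube illuminates the
anterior tracheal wall with 810 nm near-infrared light (near the
hemoglobin isosbestic point, so the signal is insensitive to oxygenation
changes), and a small board with five phototransistors taped to the
chest skin watches the transmitted light spot. When the tube moves along
the trachea, the spot moves along the sensor row, and the pattern of
sensor voltages encodes the displacement.

The package implements the full computational chain in simulation:
tissue photon transport, the detector electronics, the ratio-based
calibration/estimation algorithm, a synthetic session generator standing
in for animal experiments, and the agreement statistics used to compare
the estimator against a reference position sensor.

## Photon transport in layered tissue

The anterior neck is modeled as a five-layer slab, lumen to skin:
mucosal/submucosal/glandular tissue (1.5 mm), tracheal cartilage
(1 mm), adipose-rich soft tissue (6.5 mm), muscle-rich soft tissue
(6.5 mm), and skin (0.5 mm) — 16 mm in total. Each layer carries an
absorption coefficient $\mu_a$, scattering coefficient $\mu_s$ (both
1/cm), Henyey–Greenstein anisotropy $g$, and refractive index $n$;
`default_tissue_stack()` holds the values.

Transport follows the classic layered-slab packet scheme: step lengths
are sampled as $s = -\ln u / \mu_t$ with $\mu_t = \mu_a + \mu_s$ and the
residual optical depth carried across layer boundaries; at each
interaction the packet deposits the fraction $\mu_a/\mu_t$ of its weight
and scatters through a Henyey–Greenstein angle; every index step
(including the outer air boundaries, $n = 1$ by default) applies
unpolarized Fresnel reflection/refraction; packets below weight
$10^{-4}$ play Russian roulette with survival probability $0.1$. The
kernel is written in C++ and draws from R's RNG, so a run is fixed
bit-for-bit by `set.seed()` via the `seed` in `source_spec()`.

Two transport modes exist because the sensing question is essentially
one-dimensional. `"planar2D"` confines positions and directions to the
source–sensor plane, using the closed-form planar Henyey–Greenstein
inverse CDF
$\theta = 2\arctan\!\big(\tfrac{1-g}{1+g}\tan(\pi(u-\tfrac12))\big)$;
both the planar and the 3D phase function have mean deflection cosine
$g$, which the moment tests exploit. `"slab3D"` is full 3D transport and
returns the 2D skin exitance map needed for the off-axis rotation
sensors P4/P5 and the lobe-tilt (tube rotation) study.

The "cosine intensity distribution" of the side-firing tip is read as a
Lambertian lobe about the inward surface normal, rotated by
`tilt_angle` for rotation studies; the fiber is assumed in contact with
the mucosa, so packets launch inside the first layer with no entrance
Fresnel step. Choices the physics does not dictate are defaults, not
claims: lateral domain half-width 40 mm (beyond which packets count as
lateral escape), 0.5 mm exitance bins, 6-point moving-average smoothing.
The even smoothing window is centered as offsets $-2..+3$; at 0.5 mm
bins the residual half-bin asymmetry is far below the Monte Carlo noise.
In 3D, the 1D profile pools a ±2 mm strip around the sensor axis — a
deliberate trade of y-resolution for photon statistics at desk-scale
packet counts.

Energy bookkeeping (absorbed + skin exitance + lumen reflectance +
lateral escape = launched power) is exact up to roulette fluctuations,
which are of order $10^{-7}$ relative; the test suite bounds the error
at $10^{-3}$. The Beer–Lambert limit ($\mu_s = 0$, matched indices,
pencil beam) and the Henyey–Greenstein first moment serve as independent
oracles.

At $2\times10^6$ packets (the scale used by the tests and the acceptance
script; a laptop-minute of compute) the smoothed skin profile of the
default stack falls to half its peak at about 7.5 mm laterally, and the
simulated ratio curves show the working asymmetry: $r_{12} > r_{32}$
when the tube is pulled out ($d < 0$) and the reverse when pushed in.

## Detector board and electronics

Sensors P1–P3 sit along the tube axis at $-10, 0, +10$ mm; P4/P5 sit
±3.5 mm beside P2. Sensor $i$ integrates the exitance over a small
aperture (default half-width 0.5 mm, one bin) centered at $x_i - d$,
where $d$ is the tube displacement — positive $d$ (tube pushed inward)
moves the spot toward P3. In planar-2D sessions P4/P5 are modeled as the
P2 channel scaled by 0.8 (their peaks are lower, being off the fiber
path); 3D runs sample their true offsets from the exitance map.

The phototransistor chain is linear with rail saturation
($V = \min(5\,\mathrm{V}, \text{responsivity}_i \times I)$; no transfer
curve is available, so responsivity defaults to 1 per sensor and is the
hook for gain heterogeneity), followed by an RC low-pass (200 kΩ, 82 nF,
cutoff $1/2\pi RC = 9.7$ Hz) implemented as the matched single-pole
discrete filter with pole $e^{-2\pi f_c/f_s}$ and exact unit DC gain at
the 250 Hz sampling rate, then 14-bit quantization over $[0, 5]$ V
(round half away from zero on the level index) with optional Gaussian
noise. Ratios $r_{12}, r_{32}$ are invariant to any common gain factor
below saturation, which is why the method tolerates coupling changes
that move all channels together.

## Calibration and displacement estimation

The estimator works on two voltage ratios, $r_{12} = V_{P1}/V_{P2}$ and
$r_{32} = V_{P3}/V_{P2}$, guarded by a 0.02 V floor on $V_{P2}$ (about
65 ADC levels; a collapsed P2 signal means decoupling or an extreme
displacement, and division would amplify noise unboundedly).

Calibration measures dwell-averaged ratios at the five displacements
$-10, -5, 0, +5, +10$ mm (synthetic calibration logs dwell 2 s per
position and discard the leading 20% of each dwell, so the RC filter's
16 ms transient is numerically negligible in the average — the dwell
duration and trimming are our choices; the protocol specifies neither)
and fits four quadratic branches, each through
three nodes exactly (three points determine a quadratic; averaging
happens before fitting): `f12_high` and `f32_low` on
$\{-10, -5, 0\}$, `f32_high` and `f12_low` on $\{0, +5, +10\}$. The
"high" branch in each half-range carries the larger ratio — the better
signal-to-noise side. A branch whose vertex falls inside its half-range
cannot be inverted uniquely and is flagged.

Estimation classifies direction by $r_{12}(d)/r_{12}(0)$ (greater than
one: spot toward P1, tube moving outward/negative; less than one:
inward/positive; exactly one returns zero directly — the branch
assignment at the tie is undefined otherwise). The matching half-range
is then inverted through both its branches by quadratic root selection,
and the two estimates fuse as
$$d_{final} = w\,d_{high} + (1 - w)\,d_{low}, \qquad w = 0.95,$$
with $w$ exposed as a parameter (no optimization of $w$ is attempted).
Ratios beyond the fitted curve's reach clamp to the applicable range end
with a quality flag rather than extrapolating — extrapolation beyond the
±10 mm calibration range is exactly where outliers arise. The direction
deadband defaults to 0 (the strict rule); a nonzero deadband is
available as a hysteresis extension for noisy streams. P4/P5 feed a
separate rotation alert comparing $V_{P4}/V_{P2}$ and $V_{P5}/V_{P2}$
to their calibration baselines with a configurable fractional threshold
(default 0.30, a placeholder — the alert never enters displacement
estimation).

## Synthetic sessions

`generate_session()` emulates the bench/animal protocol: back-and-forth
sweeps over ±15 mm in 1 mm steps (one full sweep per cycle, 5 cycles
by default, 0.5 s dwell per step — a pace a human operator could hold;
the dwell is our choice, nothing in the protocol fixes it), sampled at
250 Hz through the full electronics chain, with the per-frame truth
column playing the role of the reference position sensor.

The default spot model is a closed-form pseudo-Gaussian
(σ = 7 mm, peak 3 V at unit gain, P4/P5 gains 0.8), chosen so that
sessions synthesize in milliseconds; an MC-driven mode accepts a tissue
stack for end-to-end physics realism. The pseudo-Gaussian reproduces
the qualitative features live measurements show and the simulation does
not: per-sensor gain heterogeneity, broader curves (`broadening_factor`),
peaks displaced from their nominal positions (`peak_offsets`). It does
**not** reproduce tissue heterogeneity along the sweep, contact-pressure
drift, breathing or cardiac motion — so passing round-trip tests shows
the estimator chain is correct and noise-robust at the stated levels,
not that the device achieves these errors in vivo.

Noise magnitudes are invented placeholders (nothing quantifies the real
chain's noise): additive 0.01 V, optional multiplicative fraction,
per-cycle gain drift, and — in `"manual"` mode — 0.3 mm step jitter
(the truth column records the jittered position, as a reference sensor
would) plus a per-dwell per-sensor coupling wobble (sd 0.02) standing in
for tilt and hand tremor. The coupling wobble perturbs the optics
without moving the tube, so the reference sensor cannot see it; that
asymmetry is what makes manual-mode limits of agreement wider than
linear-stage ones at equal voltage noise, directionally matching the
bench observation.

## Agreement statistics

`linear_agreement()` is ordinary least squares of estimated on reference
with $R^2$ (the square of the Pearson correlation; identical to
$1 - SSR/SST$ for simple OLS). `bland_altman()` plots-in-numbers the
method comparison: differences against pair means, with either a
constant bias (mean difference, limits at $\pm 1.96\,SD$ of the
differences) or — when the difference scatter visibly trends with
displacement — a regression bias line in the pair mean, limits at
$\pm 1.96\,SD$ of its residuals. Sample standard deviations
($n-1$) are used throughout. The regression-mode limits assume
homoscedastic residuals about the bias line; a variance-regression
model for "shrinking" limits is out of scope. `summarize_cycles()`
re-grids repeated sweeps by per-cycle linear interpolation at a 1 mm
default interval and reports the cross-cycle mean and $1.96\,SD$ band;
one cycle leaves the band undefined (flagged), two cycles offset by
$2\delta$ give exactly $1.96\sqrt{2}\,\delta$ under the sample-SD
convention.

## Numerical choices and degenerate inputs

* Quadratic inversion: if the discriminant is negative the ratio lies
  beyond the branch extremum and the estimate clamps to the vertex-side
  range end; real roots outside the range clamp to the nearest end; two
  roots inside the range is an error (precluded by the monotonicity
  flag). Near-zero curvature falls back to linear inversion; near-zero
  curvature *and* slope is a degenerate-fit error.
* The node-exactness round trip (recovery of the five calibration
  displacements to $10^{-6}$ mm) is checked with an idealized 30-bit
  ADC: the instrument's 14-bit LSB alone limits recovery to about
  0.01 mm, so the $10^{-6}$ figure is a statement about the algorithm,
  not the quantized chain.
* Roulette-killed weight is dropped rather than re-tallied; conservation
  holds in expectation with per-run error around $10^{-7}$ relative.
* Quantization ties round half away from zero; with continuous noise
  they have probability zero and the choice is recorded only for
  reproducibility.
* Problem sizes: transport tests use $10^5$–$3\times10^5$ packets with
  3-standard-error oracle bands; the half-width check and the acceptance
  script use $2\times10^6$ packets (the half-width then reproduces to
  about ±0.1 mm across seeds); lobe-tilt comparisons use $10^6$ packets
  per angle with a log-ratio band of 0.35 absorbing the residual MC
  noise at the outer sensors. These are the package's chosen study
  sizes; the full-scale counts ($3\times10^7$/$5\times10^7$) change
  nothing but the error bars.

## Known limitations

The slab approximation ignores tracheal curvature; transport is
single-wavelength, unpolarized and time-independent; the 2D mode is
true planar transport, which is one of two readings of a "2D
simulation" (a 2D slice of 3D transport would be the other) — the
half-width tolerance absorbs the difference. The session generator's
noise levels are placeholders, and the Bland–Altman analysis inherits
its usual caveats when its assumptions (in particular comparable
precision of the two methods) are violated; repeated-measures bias
methods are deliberately out of scope.
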