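---
title: "Models and methods behind ciliaphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ciliaphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaphys)
```

`ciliaphys` quantifies the electrophysiology and Ca²⁺ signalling of ependymal
motile cilia. This vignette explains the models the package implements, the
assumptions behind them, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the procedures in the field are
conventionally under-specified.

## 1. The equivalent circuit of whole-cilium access

Breaking into a cell through the tip of a motile cilium puts the ciliary
lumen in series with the pipette: the recording sees a series (access)
resistance `R_series` in front of the cell membrane's capacitance `C_m` and
resistance `R_m`. The package treats the cilium as a **lumped** access
resistor — a single `R = ρl/(πr²)` for a cylinder of length `l` and radius
`r` — not as a distributed cable. That is adequate because the cilium's own
membrane area (~9 μm², ~0.09 pF) is a tiny fraction of the cell's (~18.5 pF),
so almost all charging current flows through the lumen into the cell. The
internal resistivity `ρ` of a cilium is not known; the default 150 Ω·cm
assumes cytoplasm-like resistivity and is a free parameter of
`membrane_constants()`. With the defaults the lumen contributes ~350 MΩ,
matching the order of measured whole-cilium access resistances (≈180 MΩ
pipette + cilium in series with a partially uncoupled cell — the lumped
estimate is an upper bound for an ideally insulated cable).

Derived relations (all in `circuit_model`):

* `cylinder_surface_area()` uses `A = 2πr(r+h)`; the end caps contribute ~1%.
* `membrane_capacitance_from_area()` applies 1 μF/cm² = 0.01 pF/μm², the
  standard specific capacitance of biological membranes.
* `clamp_time_constant()` returns `τ = C_m·(R_series ∥ R_m)`; both this and
  the ideal `R_series·C_m` form are available because reported time constants
  conventionally quote the ideal form.
* `membrane_voltage()` implements `V_m = V_cmd − I_m R_series` with the
  inward-negative sign convention, so an inward current makes the membrane
  *more positive* than the command — the distortion that shifts apparent
  activation curves in high-access recordings.
* `channels_per_cell()` parses the count formula as `N = I_m/(P_o·i)`, the
  only dimensionally consistent reading, and `channels_per_cilium()` scales
  by the capacitance ratio. Capacitance substitutes for membrane area because
  the two are proportional at fixed specific capacitance; both routes agree
  to three significant figures for the default geometry.
* `nernst_potential()` evaluates `RT/zF` from physical constants at the
  supplied temperature (default 22 °C, room-temperature recording); nothing
  is hard-coded. The default pipette K⁺ for E_K calculations is 130.5 mM
  (121.5 methanesulfonate salt + 9 KCl), ignoring the small KOH titration.

## 2. Capacitive-transient analysis

`analyze_capacitive_transient()` follows the classical charge method: average
sweeps, estimate the steady-state current from the **final 20%** of the step
(configurable — the window must be long relative to τ; the bundled tests use
a 100 ms step against a worst-case τ of 9 ms), subtract it, integrate the
transient by the trapezoidal rule from step onset to step end to get `Q`,
then `C_m = Q/|ΔV|`. The time constant comes from an explicit
single-exponential least-squares fit (Levenberg–Marquardt, seeded with
`Q/amplitude`, which is exact for an ideal RC), starting at the transient
extremum. A charge-based τ could be read instead as `Q/(ΔV/R_s)`; the fit is
the default because it is robust to small baseline errors that bias the
integral. `R_series = τ/C_m` closes the triplet.

Note one genuine ambiguity in how such numbers are conventionally reported:
`τ/C_m` computed from *population means* of τ and C_m does not equal the
mean of per-recording `R_series` (169 vs 180 MΩ for typical whole-cilium
values). The package always computes per-recording values and leaves
averaging to the caller.

`subtract_leak()` implements P/N-style leak subtraction exactly as practised:
three hyperpolarizing responses are summed, inverted, scaled by
`ΔV_test/(3|ΔV_leak|)` and subtracted. For any linear circuit the residual is
identically zero — this linearity is asserted in the tests over several (R, C)
combinations and is independent of the circuit values.

`offline_filter()` is a zero-phase Gaussian low-pass with
`σ_t = √(ln 2)/(2π f_c)` (the −3 dB convention) and unit DC gain, the filter
shape conventionally used for display filtering of single-channel records.
Its white-noise variance reduction equals `Σk²`, which the tests check
against the analytic `1/(2σ√π)`.

`open_probability()` is the time-average estimator `⟨I⟩/i`, valid for
baseline-subtracted, leak-free sweeps from a patch with one channel (values
outside [0, 1] are clamped with a warning, the signature of multi-channel
patches). `amplitude_histogram()` supports all-point and open-point modes;
open points are samples beyond 0.9 of the full amplitude from baseline, the
conventional fraction for isolating the open-level distribution.

## 3. The ratiometric Ca²⁺ pipeline

The pipeline fixes the order of operations as: saturation mask → background
subtraction → ratio → low-signal mask. Masking on the Ca²⁺-insensitive
mCherry channel avoids biasing pixel selection by the Ca²⁺ signal itself.
A denominator floor (1% of the red dynamic range) drops pixels whose
background-subtracted red signal would make the ratio numerically unstable;
the count of dropped pixels is reported, never silently absorbed.

**Bleed-through.** Under non-sequential scanning (needed so a beating cilium
occupies the same pixels in both channels) a fraction α of the green GCaMP6s
emission is detected in the red channel. α is estimated from a red-free,
GCaMP6s-only specimen by ordinary least squares of red-channel (leak) ROI
means against green ROI means, and the correction is the ratio offset
`A_c = R_raw − α`. In the generator's forward model (leak `α·G` added to the
red channel) the measured ratio `G/(R+αG)` is a Möbius transform of the true
Hill response — which is *again* a Hill function in [Ca²⁺] with the same
`n_H` and slightly shifted `R_min`, `R_max`, `EC50` (a ~2% EC50 shift at
α = 0.03). Two consequences, both verified in tests: the Hill fit to
corrected calibration data converges cleanly, and inversion of new
measurements through the *fitted* curve is unbiased even though the fitted
parameters differ from the generator truth by O(α). Sequential-scan data
carry no bleed-through and are calibrated raw.

**Hill calibration.** `fit_hill()` does weighted least squares of
`A_c = R_min + (R_max−R_min)[Ca]ⁿ/(EC50ⁿ+[Ca]ⁿ)` with bounds `R_min ≥ 0`,
`n_H ∈ (0.3, 6)`, starting values from the data range and the log-midpoint of
the concentration span. Calibration solutions should span the transition
(50 nM–10 μM covers sensible GCaMP6s EC50s). Flat data return a flagged
degenerate fit rather than an error. `ratio_to_calcium()` inverts
analytically and refuses ratios outside the open interval `(R_min, R_max)`,
naming the violated bound — extrapolating a saturating sensor is meaningless.

**Operating point.** The published calibration for this sensor reports only
its operating point — corrected ratio 0.2 at 165 nM resting ciliary [Ca²⁺] —
so `sensor_hill_defaults()` pins the default simulation truth to that point:
with `R_min = 0.05`, `R_max = 1.2`, `n_H = 2` fixed at GCaMP6s-like values,
the implied `EC50` is 426 nM. Synthetic-truth recovery, not any published
parameter set, is the acceptance standard for this module.

Free [Ca²⁺] of calibration solutions is an *input* (buffer speciation is done
with external tools); sensor photophysics beyond additive Poisson–Gaussian
noise (bleaching, pH) and motion correction of beating cilia are out of
scope, the latter because non-sequential scanning removes the need.

## 4. Motility and flow

`reslice_kymograph()` samples frames along a polyline at ~1 px spacing with
bilinear interpolation (0-based pixel-centre convention, physical units
attached at construction), optionally averaging across a perpendicular width
— the ImageJ reslice operation. An axis-aligned line reduces exactly to
row/column extraction, which the tests use as an oracle.

`beat_frequency()` counts peaks of the line-integrated intensity trace.
Peak criteria are not conventionally reported with kymograph counts, so the
package fixes and exposes them: prominence ≥ 25% of the window's amplitude,
minimum separation from a 25 Hz ceiling. Counting quantizes frequency at
1/window (±0.5 Hz for the 2 s default), which sets the recovery tolerance.
A trace whose total amplitude is within 8 robust noise SDs (from
frame-to-frame differences) is reported as 0 Hz with a low-signal flag
rather than counting noise peaks.

`front_velocity()` reads a base-to-tip line scan: per position, the crossing
time is the first time the fluorescence change exceeds 50% of that position's
plateau change; the velocity is the least-squares slope of position vs
crossing time over the **distal half** of the span (the proximal cilium can
show a second, slower apparent velocity when two indicators with different
kinetics are present, so the distal span is the conventional analysis
region). On a constant-velocity wave this is exact to frame quantization; on
a diffusion profile it reports the chord ("apparent") velocity, and crossing
times scale as position² — the diffusion-mode generator solves the clamped-
reservoir/no-flux-tip problem by its eigenfunction series, so this scaling
law is testable away from the tip (reflection contaminates crossings within
~0.4 of the length from the tip).

`track_beads()` links per-frame detections greedily by nearest neighbour
under a gate distance — adequate for sparse, fast, unidirectional bead
fields; global assignment would only matter for dense crossing traffic,
which the flow assays do not produce. Tracks shorter than 4 frames are
discarded (with a count), matching standard practice. `bead_velocity()`
reports pathwise speed (path length / time), what frame-by-frame manual
tracking measures; the displacement-based speed is also returned because the
pathwise estimator has a known upward bias for stationary jittery beads
(expected step `σ√π` per frame for 2-D Gaussian jitter of SD σ), which the
tests quantify.

## 5. Synthetic data: what is and is not emulated

Every generator takes a `sim_config(seed)` and derives one RNG stream per
artifact from the master seed via a fixed offset + counter scheme, so outputs
are bit-reproducible and adding a generator call never perturbs other
streams. Every artifact carries a machine-readable truth record; analyses
are validated only against truth records.

* `simulate_patch_recording()` — exact piecewise-exponential solution of the
  access + parallel-RC circuit (step-on/step-off superposition), additive
  Gaussian current noise (default 1 pA RMS, chosen to visually match
  published traces; no noise magnitudes are published). The closed form is
  cross-checked against brute-force explicit-Euler integration to < 0.1%.
* `simulate_single_channel()` — continuous-time two-state Markov gating per
  channel (exponential dwells, stationary start), point-sampled at the
  digitization times. The sampler warns when mean dwells fall under
  5 samples.
* `simulate_cav_current()` — Boltzmann steady-state activation with
  first-order kinetics; with `apply_rs_error` the membrane voltage is solved
  self-consistently per time step from `V_m = V_cmd − I·R_series` by damped
  fixed-point iteration (tolerance 1 μV, 100 iterations, divergence reported
  as the loss-of-clamp regime). The truth record keeps the undistorted
  current, so the hyperpolarized shift of the distorted I–V peak is testable.
* `simulate_calibration_stack()` — cilia as anti-aliased Gaussian-profile
  curves (σ ≈ 1 px) of physical length 11.5 μm at 0.1 μm/px; red carries
  expression, green = red × Hill([Ca²⁺]), leak α·green into red under
  non-sequential scanning; Poisson shot noise (configurable gain; 0 disables)
  plus Gaussian read noise.
* `simulate_beating_stack()` — a cilium sweeping a fixed analysis line:
  position oscillates sinusoidally and the cilium is visible during one half
  of each cycle (the stroke crossing the line), so line-integrated intensity
  pulses once per beat. A piecewise-constant frequency schedule emulates
  drug wash-ins.
* `simulate_front_linescan()` — constant-velocity sigmoidal fronts, or the
  finite-domain diffusion solution above; an optional first-order low-pass
  stands in for indicator binding kinetics (a uniform delay, so front slopes
  are unaffected). Indicator kinetics are configurable, not fitted — rise
  times differ between indicators and are not identifiable from these data.
* `simulate_bead_field()` — beads entering at staggered times, drifting at
  per-bead velocities around the mean with Gaussian positional jitter,
  leaving the field of view; emits anonymous per-frame detections as a
  detector would.

What passing these tests shows — and does not. The generators reproduce the
*statistical structure the analyses assume* (exponential relaxations, Markov
gating, Hill-governed fluorescence, periodic kymographs, drifting
detections). Real recordings add what the generators deliberately omit:
pipette drift and seal instability, metachronal interference between
neighbouring cilia, indicator bleaching, out-of-focus light, and detection
failures in dense bead fields. Recovery on synthetic data therefore validates
the estimators' correctness and calibration, not their robustness to every
experimental artifact.

## 6. Problem sizes and tolerances

The bundled tests run the generators at sizes chosen to make sampling error
small relative to the asserted tolerances: 150-sweep transient averages on a
4×4 (C_m, R_series) grid (2% noiseless, 10% at default noise), 9 × 400 ms
gating sweeps for the P_o = 0.32 recovery (compared within 3 SE, the SE
estimated from between-sweep scatter), 7-level calibration images of 160²
pixels, 2 s of beating at 200 frames/s (±0.5 Hz counting quantization), 15 s
line scans for the diffusion scaling law (exponent 2.0 ± 0.1), and 12–15
beads over 4 s for velocimetry (5% at 10% jitter). `scripts/acceptance.R`
re-runs the same conditions end-to-end from a single command-line seed.
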