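---
title: "Respiratory-position variability in LV torsion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-position variability in LV torsion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtorsion)
```

## The measurement and its confound

LV torsion is quantified from two short-axis slices: per frame, each slice's
rotation angle φ(t) about the LV long axis is measured relative to
end-diastole, and torsion is τ(t) = (φ_a(t) − φ_b(t)) / d, with d the
basal–apical distance *taken from the image-plane metadata*. Peak torsion is
the maximum of τ(t).

The confound this package models: the two slices are acquired in separate
breath-holds, and the end-expiratory diaphragm position — hence the heart's
long-axis position relative to the fixed imaging planes — varies between
breath-holds by several millimetres. The slice therefore samples the
ventricle at an *effective* longitudinal position `planned + coupling · Δz`,
while the metadata (and therefore d) still reports the planned position.
With a twist profile that varies along the long axis, the measured twist
difference changes but the divisor d does not, so torsion inherits the
respiratory variance. For the linear profile this is exact and closed-form:

τ_peak = g · (1 + coupling · (Δz_a − Δz_b) / d),

where g is the configured twist gradient. `torsion_oracle()` implements
this; it is the independent oracle against which the entire
simulate → unwrap → smooth → fit → rotate → divide pipeline is tested to 2%.

## The phantom (stated world)

`phantom_config()` defaults are the acquisition's stated conditions:
displacement encoding k = 0.06 cyc/mm, pixel spacing 2.8 mm, temporal
resolution 34 ms, and a twist gradient of 3.4 °/cm (the measured healthy
mean). The geometry (end-systolic long-axis length 88 mm, end-diastolic
endocardial/epicardial radii 20/30 mm, 10% radial shortening, 24 frames,
48-px grid) is chosen once at typical adult values; none of these affect
the torsion statistics to first order because torsion is a *gradient*
measurement. Five slice planes are spread evenly over the end-systolic
long-axis length; the 2nd and 4th are basal and apical, so d = 44 mm.

Kinematics: every myocardial material point (pixel at end-diastole) is
rotated about the slice centroid by θ(z, t) = θ_ES(z) · s(t) and contracted
radially by 1 − c·s(t). For the linear profile θ_ES(z) = g·(z − L/2)/10 with
z in mm, so the base rotates clockwise and the apex counter-clockwise
(viewed foot-to-head, counter-clockwise positive) and torsion is positive.
The cycle shape s(t) is 0 at end-diastole, rises as a quarter-sine to
exactly 1 at end-systole (40% of the cycle, snapped to a frame so the peak
is sampled), then relaxes as a quarter-cosine; the diastolic tail is
unconstrained by the quantities studied here, since peak torsion is the
endpoint. A sigmoid (tanh) profile with the same mid-ventricular gradient is
available to probe nonlinearity, but the oracle above holds only for the
linear profile.

Phase images are `wrap(2πk·u + ε)` with ε ~ N(0, 0.1² rad) i.i.d. inside the
myocardial mask (default chosen small enough that unwrapping is
unambiguous at physiologic displacements; the wrap convention is half-open,
`wrap(π) = −π`).

## The respiratory model

End-expiratory positions are zero-mean truncated normal draws with SD
3.3 mm, truncated at ±10.2 mm. The truncation bound is a *calibration*: the
reported within-subject summary (10-breath-hold range 10.2 mm, SD 3.3 mm)
has range/SD ≈ 3.09, which is what an (essentially) untruncated normal
yields for 10 draws — E[range of 10] ≈ 3.08·SD. Truncating at ±range keeps
draws physiologic while preserving E[range of 10 draws] ≈ 10.08 mm, within
1.2% of the target (a ±range/2 bound would shrink it to ~7.4 mm and break
the calibration). This choice was made once, from the summary statistics,
and is not revisited.

Navigator gating restricts a draw to a ±3 mm window about the window center
(rejection from the same distribution; a zero-width window pins the draw at
the center). The wide ±50 mm monitoring window never rejects. The diaphragm
offset is transmitted to the cardiac long-axis position with a coupling
factor (default 1.0, exposed as a parameter because the true coupling is not
published); in-plane translation/rotation of the heart with respiration is
ignored — the modeled mechanism is through-plane translation, which is the
first-order effect on a gradient measurement.

Experiment 1 (enforced variability): 10 scout breath-holds give each
subject's min/mid/max end-expiratory positions ("middle" = recorded position
closest to the median, ties toward the smaller value — a documented choice,
unspecified in the source protocol); basal and apical slices are acquired
with the window at each position, and the middle pair is repeated, 8
acquisitions in all. Experiment 2 (natural variability): 10 basal + 10
apical acquisitions per protocol, alternating in temporal order, free
breath-holds vs a single gated window at 0.

## Reconstruction

* **Unwrapping** is quality-guided region growing (path-following): pixels
  are visited in decreasing quality, defined as the negative variance of the
  wrapped phase gradients to the 4 masked neighbours, and each new pixel is
  shifted by the 2π multiple bringing it within π of the mean of its
  already-unwrapped neighbours. The seed is the masked pixel of maximum
  magnitude intensity (the interactive seeding of clinical tools has no
  place in a test pipeline). Mask pixels not 4-connected to the seed are
  excluded with a warning. The independent oracle is 1-D cumulative
  unwrapping along rows; agreement up to one global 2π constant is asserted
  on 100 random smooth ramps.
* **Global 2π constant**: resolved per frame and direction by choosing,
  among shifts of {−1, 0, +1} wraps, the one minimizing the magnitude of the
  spatial median displacement. This is well-posed because bulk myocardial
  displacement is far below one encoding period (16.7 mm at k = 0.06); for
  a field whose true median is itself near half a period the rule is
  ambiguous by construction, which is why it is applied to displacement
  fields, not arbitrary phases.
* **Smoothing** is a mask-restricted, renormalized Gaussian (default SD
  1 px); **temporal fitting** is least squares on the basis t, t², …, t^p
  (default p = 4) with no intercept, so fitted displacement is exactly zero
  at end-diastole. Both defaults are unpublished processing details; they
  are validated by the end-to-end 2% parameter-recovery acceptance test
  (the quartic introduces a ≈0.5% peak underestimate at 24 frames, ≈1.5%
  at 12 frames — the reduced-frame configuration is therefore used only in
  directional tests, never in 2%-accuracy assertions).

## Quantification

Rotation per frame: subtract the frame's mean in-plane displacement (bulk
translation correction — a translation must not read as rotation), then
average the per-point signed angles atan2(cross, dot) between (p₀ − c) and
(p_t − c) with a circular mean; c is the centroid of the end-diastolic
endocardial boundary (mask pixels adjacent to the blood-pool cavity). All
masked pixels contribute (whether the original analysis used a mid-wall
subset is unknown; at these angles the difference is negligible). The
circular mean avoids ±180° pathologies and coincides with the arithmetic
mean at physiological angles. Peak torsion is max over frames of τ(t), not
a fixed-frame value.

## Variability statistics: conventions

* Duplicate-pair RMSE: |x₁ − x₂|/√2 — the within-pair error-variance
  convention (x₁ − x₂)²/2. The alternative reading, MSE about the pair mean
  ((x₁ − x₂)²/4), is rejected and the choice isolated in
  `rmse_consistent()`.
* Permutation RMSE: MSE of the nine permutations against each middle-window
  reference separately, averaged, then square-rooted.
* Limits of agreement: 1.96·SD (n−1) of paired differences. Experiment 1
  uses the per-subject reference-pair differences; experiment 2 uses
  successive differences of the 2n pairings in temporal order (2n − 1 per
  subject) — "consecutive pairs" is ambiguous, so the disjoint-pair reading
  is available behind `loa_flavor = "disjoint"`.
* Binomial coverage: pooled over subjects (N = subjects × 9), center = each
  subject's reference-pair mean, one-sided p = P(X ≤ k | N, 0.95).
* Experiment-2 correlation pools both protocols (2 points per subject),
  the only reading consistent with the published degrees of freedom;
  per-protocol correlation is a matter of subsetting the inputs.
* Degenerate paired t-tests (zero-variance differences) return p = 1 with a
  warning rather than an error.

## Sample size

n = ceil(f(α, P)·σ²·2/δ²) with f computed from normal quantiles (not a
lookup), σ = LoA/1.96, δ defaulting to 10% of the measured mean torsion.
Ceiling rounding is the package's choice (sample sizes are integers at
least as large as the formula value) and reproduces the published 15 and
26 from the printed ±0.56 and ±0.74 limits of agreement.

## What the synthetic world establishes — and what it does not

The generator emulates: wrapped displacement-encoded phase with noise, the
planned-vs-effective slice-position confound, both acquisition protocols,
and empirically calibrated end-expiratory variability. It does not emulate:
pulse-sequence physics (spiral readout, echo suppression, through-plane
dephasing), contour-drawing variability (masks are exact), in-plane
respiratory motion, beat-to-beat physiologic variation, or patient-specific
breath-hold behaviour. Green tests therefore establish that the
*quantification and statistics* are correct and that through-plane
respiratory offsets alone reproduce the published ordering (permutation
RMSE > duplicate RMSE; breath-hold SD > navigator SD; torsion error grows
with end-expiratory range) — they do not re-measure the published empirical
variability magnitudes, which carry sources of error this model
deliberately omits.

## Numerical and engineering choices

* Determinism: every stochastic stage draws from a named substream derived
  from one master seed (31-bit hash), so identical configs + seed give
  bit-identical sessions and reports, and stages can be re-run in
  isolation.
* Session containers are in-memory R objects (written as `.rds` by the CLI);
  analysis artifacts are CSV/JSON with a config hash and seed recorded for
  provenance. No HDF5 dependency is available in the supported environment.
* Degenerate inputs: zero-width windows, zero noise, zero twist, zero SD
  respiratory models, and disconnected masks are all defined behaviours
  with tests, not errors — except where the quantity is undefined (zero
  slice distance, fewer than 3 breath-holds, polynomial order ≥ frame
  count), which raise errors.
* The reduced phantom used in replicate sweeps (32-px grid, 12 frames)
  changes only resolution, not geometry, kinematics or respiratory
  parameters; it is used where the assertion is directional or count-based.

## Known limitations

Eulerian pixel displacements are treated as material-point trajectories
(valid at these motion amplitudes, ~8 mm against a 10 mm annulus
thickness); the twist profile is stationary over the cycle shape; the
navigator measures the diaphragm without error; and the coupling between
diaphragm and cardiac long-axis position is a single scalar. All are
first-order simplifications consistent with the mechanism under study.
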