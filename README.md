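# lvtorsion

Left-ventricular (LV) torsion — the base-to-apex gradient of myocardial
rotation, τ = (φ_a − φ_b) / d in °/cm — is a sensitive marker of cardiac
function, but its test–retest variability is notoriously large. One
under-appreciated cause is respiratory: basal and apical short-axis images
are acquired in *separate* breath-holds, the end-expiratory diaphragm
position differs by up to ~10 mm between breath-holds, and the heart
translates through the fixed imaging planes accordingly. The slice-position
metadata used to compute the inter-slice distance d cannot see this, so the
measured twist difference is divided by the wrong effective distance, and
torsion acquires respiratory-position-driven variance. Gating acquisitions
with a respiratory navigator (accepting data only inside a ±3 mm diaphragm
window) removes most of this variance.

`lvtorsion` reproduces this whole story end-to-end on synthetic data, for
imaging scientists and biostatisticians who want to study or teach the
effect without scanner time:

* **Synthetic DENSE-style acquisitions** (`phantom_config()`,
  `simulate_experiment1()`, `simulate_experiment2()`): an annular LV
  cross-section with a linear longitudinal twist gradient (default
  3.4 °/cm) and radial contraction, displacement-encoded into wrapped phase
  images (k = 0.06 cyc/mm, 2.8 mm pixels, 34 ms frames) under a
  truncated-normal end-expiratory offset model (SD 3.3 mm, 10-breath-hold
  range 10.2 mm) and either protocol: enforced min/mid/max navigator window
  positions with a repeated middle pair (experiment 1), or consecutive
  breath-holds vs navigator-gated scans (experiment 2).
* **Reconstruction** (`build_trajectories()`): quality-guided
  region-growing phase unwrapping (Rcpp), phase→displacement inversion,
  mask-restricted Gaussian smoothing, and a through-zero polynomial
  temporal fit.
* **Quantification** (`rotation_curve()`, `torsion_curve()`): slice
  rotation about the end-diastolic endocardial centroid (circular mean,
  bulk-translation corrected), twist, and torsion using plane metadata
  only for d — exactly the confounded quantity a scanner workflow computes.
* **Variability statistics** (`nine_permutations()`, `rmse_consistent()`,
  `rmse_permutations()`, `limits_of_agreement()`,
  `binomial_within_limits()`, `consecutive_pairing()`,
  `protocol_sd_comparison()`, `correlate()`).
* **Sample sizes** (`factor_f()`, `required_n()`): n = f(α,P)·σ²·2/δ² with
  f = (z₁₋α/₂ + z_P)²; f(0.05, 0.90) = 10.5, and σ taken from 95% limits
  of agreement (σ = LoA/1.96).

## Worked example

A reduced-size run of the enforced-variability protocol (8 synthetic
subjects, 32-px grid, 12 frames; ~25 s on one CPU):

```r
library(lvtorsion)
config <- run_config(experiment = 1,
                     phantom = phantom_config(grid_size = 32, n_frames = 12,
                                              phase_noise_sd = 0.05),
                     n_subjects = 8, seed = 11)
report <- run_experiment(config)
print(report)
```

```
<run_report> experiment 1 (hash 5e27dd67, seed 11)
  mean torsion 3.26 deg/cm, delta 0.326 deg/cm
<variability_report> experiment 1, 8 subject rows
  RMSE permutations: 0.374 +/- 0.086 deg/cm
  RMSE consistent:   0.131 +/- 0.138 deg/cm (65% lower)
  LoA (consistent): +/-0.54 deg/cm
  binomial coverage: 63/72 within limits, p = 0.00962
  sample sizes:
    enforced     LoA +/-0.71 -> n = 26
    consistent   LoA +/-0.54 -> n = 16
```

Reading this: the mean measured torsion (3.26 °/cm) recovers the
configured 3.4 °/cm gradient up to the reduced temporal resolution; torsion
RMSE across the nine min/mid/max window permutations (0.374 °/cm) is much
larger than the duplicate-pair RMSE at a consistent window (0.131 °/cm);
the binomial test rejects 95% coverage of the permutations by the
consistent-position limits of agreement (p = 0.0096); and enforcing a
consistent end-expiratory position shrinks the per-group sample size needed
to detect a 10% torsion difference (26 → 16 subjects here). The same run
with `experiment = 2` contrasts consecutive breath-holds against
navigator-gated scans.

The command-line interface wraps the same pipeline:

```sh
Rscript -e 'lvtorsion::lvtorsion_cli()' run-all --experiment 1 --seed 1 --out outdir
Rscript -e 'lvtorsion::lvtorsion_cli()' samplesize --sigma 0.2857 --delta 0.34
```

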