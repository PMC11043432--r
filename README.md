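# gridclock

Grid cells in the entorhinal cortex fire on a hexagonal lattice, and
their conjunctive activity leaves a direction-dependent trace in fMRI:
BOLD amplitude during (real or imagined) movement is modulated
sinusoidally in the movement direction θ with 60° periodicity
("hexadirectional" or 6-fold coding), while a square-grid geometry
shows up as 90° (4-fold) periodicity.  `gridclock` implements the
complete analysis pipeline for detecting such n-fold symmetry during
imagined navigation of a clock-face environment, for researchers who
want to run, stress-test or power-analyse this design without access
to raw MRI data:

- **Design generation** — the clock space is a dodecagon (numbers 1–12,
  12 at top); valid paths are the 36 chords of circular distance 3–5,
  whose traversal directions are multiples of 15°.  `build_session()`
  produces a fully counterbalanced 8-run session (192 trials): every
  run covers all 24 direction bins once with a 6/12/6
  short/medium/long mix, uses each number as an endpoint exactly four
  times, chains trials end-to-start with "jump" cues where chaining
  breaks, and balances left/right target judgments within and across
  runs.  `write_events()` emits BIDS-style events TSVs.
- **Synthetic BOLD** — `simulate_subject()` plants
  `baseline · (1 + g · cos(n(θ − φ)))` responses voxel-by-voxel (von
  Mises phase jitter, log-normal gain heterogeneity), convolves with
  the canonical double-gamma HRF and adds drift plus private and
  ROI-shared AR(1) noise.
- **Quadrature-filter estimation** — per voxel, the parametric
  modulators cos(nθ) and sin(nθ) give betas (β₁, β₂), orientation
  φ = atan2(β₂, β₁)/n and amplitude √(β₁² + β₂²);
  `crossval_symmetry()` runs the four-way cross-validation (estimate φ
  on three forward/backward run pairs, test the realigned regressor
  cos(n(θ − φ)) on the held-out pair) and returns the held-out
  symmetry magnitude plus aligned/misaligned direction-bin profiles.
- **Circular statistics** — `rayleigh_test()` for clustering of grid
  orientations across subjects, projected into fold-space.
- **Path integration** — scoring of the real-world homing task:
  standardization-walk correction factors (C_f = d_true/d_reported),
  presumed-start coordinates from each stop's distance and pointing
  report, per-segment errors and PI performance = 1/mean error.
- **Group inference** — questionnaire scoring (Route/Survey/dRS),
  Shapiro–Wilk-gated t vs Wilcoxon tests (Pratt zero handling),
  Bonferroni levels, Levene checks, correlations and
  group-by-covariate interaction models, assembled by
  `build_report()`.

## Worked example

```r
library(gridclock)

session <- build_session(seed = 1)
spec    <- group_spec(fold_n = 6L, roi_phase_deg = 23)
subject <- simulate_subject(session, spec, seed = 5)
est     <- crossval_symmetry(subject, fold = 6)
est
#> <grid_estimate> 6-fold: beta = 2.975 (phis: 20.5, 22.1, 20.8, 21.3)
phase_distance(mean(est$per_fold_phis), 23, fold = 6)
#> [1] 1.808351
crossval_symmetry(subject, fold = 4)$fold_beta
#> [1] -0.08434056
```

A subject simulated with a 6-fold grid oriented at 23° is recovered
with a held-out modulation beta of about 3 (the planted
`baseline × gain` = 100 × 0.03) and an orientation error under two
degrees, while the 4-fold control model's held-out beta stays within
the measurement noise.  At the group level:

```r
records <- simulate_study(n_per_group = 19, seed = 1)
report  <- build_report(records)
report
#> <group_report> sighted vs blind
#> flags:
#>   fold6_sig_group1           TRUE
#>   fold6_sig_group2           FALSE
#>   fold4_sig_group1           FALSE
#>   fold4_sig_group2           TRUE
#>   fold4_group2_gt_group1     TRUE
#>   rayleigh_sig_group1_fold6  FALSE
#>   rayleigh_sig_group2_fold4  TRUE
```

The synthetic sighted-like cohort shows 6-fold coding with uniform
orientations; the blind-like cohort shows 4-fold coding, larger 4-fold
magnitude, and orientations clustered near 30° off the vertical axis.

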