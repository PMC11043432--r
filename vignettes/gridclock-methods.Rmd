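---
title: "Models and methods behind gridclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gridclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gridclock` is a pipeline for detecting n-fold rotational symmetry of
direction-tuned BOLD signals — the fMRI signature of entorhinal grid
coding — during imagined navigation of a clock-face environment.  This
vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## The clock space and session design

The environment is a regular dodecagon: clock numbers 1–12 on a unit
circle, 12 at the top, numbers increasing clockwise.  Direction angles
use the mathematical convention (counterclockwise from east), under
which every chord direction is a multiple of 15°.  The zero reference
is arbitrary for the symmetry analysis — the whole pipeline is
invariant to a global rotation of angles, which the test suite checks
to 1e-10.

Valid paths are chords of circular distance 3, 4 or 5 (short / medium
/ long).  Adjacent-number chords, diameters (which cross the centre)
and distance-2 chords are excluded, leaving 36 unique paths and 72
directed traversals.  A geometric fact worth recording: directions
that are multiples of 30° can only be produced by medium chords (two
candidates each), while odd multiples of 15° are served by two short
and two long chords.  Consequently the run-level constraint set — all
24 directions once, 6/12/6 length mix — forces every medium chord into
the 30°-multiple bins, and the remaining freedom is which of the two
candidates serves each bin and how short/long chords split the odd
bins.

`choose_path_set()` resolves that freedom with a randomised
backtracking search under three constraints: one directed path per
direction bin, 24 distinct unordered chords (a chord may not appear in
both directions), and every number used as start-or-end exactly four
times.  The search is exact (it backtracks rather than retries
blindly) with a bounded node budget and restarts; an unsatisfiable
budget raises an error rather than returning a partial design.

Trial order within a run maximises end-to-start chaining greedily with
random restarts; positions where the chain breaks receive a "jump" cue
(0.5 s instruction + 4 s reorientation).  Timing per trial: start cue
0.5 s, 0.5 s gap, end cue 0.5 s, imagination 4–6 s (uniform on 0.5 s
steps — the jitter distribution is otherwise unspecified in the
paradigm), target cue 0.5 s, 2 s response window, 0.5 s inter-trial
gap.  Target numbers must differ from the path endpoints and must not
be circularly adjacent to the end number; the left/right ground truth
is the sign of the cross product between the movement vector and the
end-to-target vector, validated in the tests against an independent
rotate-the-frame oracle over all 720 admissible path-target
combinations.  Sides are balanced 12/12 within each run and 2/2 across
the four runs presenting each directed trajectory.  Sessions interleave
forward and backward runs (F B F B F B F B); backward runs traverse
the same chords in the opposite direction.

## Synthetic BOLD model

During each imagination period with direction θ the neural signal of
voxel v is a boxcar of amplitude

    baseline · (1 + g_v · cos(n · (θ − φ_v)))

where n is the planted symmetry, φ_v the voxel's grid orientation and
g_v its modulation depth.  Voxel orientations scatter around the ROI
orientation by a von Mises draw in fold-space (concentration
`phase_jitter_kappa`, default 8); voxel gains are log-normal around
the subject gain (sdlog 0.3).  Auditory cues, target and response
periods and jump cues evoke fixed-amplitude responses (default 2
signal units).  Everything is convolved with the canonical double
gamma HRF (peak ≈ 5 s, undershoot 16 s, ratio 6, 32 s support) at 16
microtime bins per TR; the discrete convolution is scaled by the
microtime step so a sustained boxcar peaks near the HRF integral
independent of resolution.

Noise has three parts: slow drift along the leading discrete-cosine
components (per-voxel random coefficients, SDs 30/20/10), voxel
private AR(1) noise (innovation SD 10, lag-1 coefficient 0.3), and an
ROI-wide AR(1) component shared by all voxels (innovation SD 30).
The shared component matters: with independent voxel noise alone, ROI
averaging over ~110 voxels and eight runs would drive per-subject
beta uncertainty three orders of magnitude below the group mean,
giving group effect sizes in the tens — nothing like the d ≈ 0.6–1
regime this class of experiment reports.  The shared term caps the
benefit of spatial averaging and puts the per-subject measurement SD
at roughly a quarter of the planted group-mean beta.  Between-subject
variability of modulation depth (`gain_between_sdlog = 0.8`,
log-normal, mean-preserving) supplies the rest of the cohort
variance, landing group-level Cohen's d near 1.

Defaults: TR 1 s, 110 voxels (the scale of an entorhinal mask at 3 mm
resolution), subject gain 0.03 on baseline 100 (a 3 % modulation,
amplitude 3 signal units against private innovation SD 10 — "moderate"
single-voxel SNR 0.3), behavioural accuracy 0.95/0.92 for the two
emulated cohorts.

What the generator does **not** emulate: spatial smoothness beyond the
single shared component, physiological noise spectra, motion (the
nuisance matrix is accepted but zeros by default), susceptibility
artefacts, and any systematic relation between behaviour and the
neural signal.  Passing tests therefore show that the estimator and
inference chain are correct and calibrated under the stated
generative model — not that the pipeline is robust to every artefact
of real entorhinal data.

## Quadrature-filter estimation and cross-validation

Per run, the design matrix holds the imagination boxcar, the two
mean-centred parametric modulators cos(nθ) and sin(nθ) (centred
across trials before convolution, as in standard parametric
modulation; they are near-orthogonal on the balanced design and are
not serially orthogonalised), a cue regressor, a jump regressor, a
target-to-response regressor, a DCT high-pass basis below 1/128 Hz
(`floor(2 · T · f)` columns) and an intercept.  Ordinary least
squares is fitted per voxel; rank deficiency falls back to the
pseudo-inverse with a warning rather than failure.

The cross-validation splits the eight runs into four held-out pairs,
each one forward plus one backward run (runs 1+2, 3+4, 5+6, 7+8 under
the interleaved layout — the pairing is otherwise arbitrary).  For
each iteration, (β₁, β₂) are estimated per voxel on the six training
runs — fitted run by run and averaged, which keeps run-specific drift
and nuisance structure out of the estimate and is equivalent to a
pooled fit on a balanced design — and converted to a voxel
orientation `atan2(β₂, β₁)/n` and amplitude `√(β₁² + β₂²)`.  The
full-quadrant `atan2` matters: a literal arctangent of the ratio
conflates (β₁, β₂) with (−β₁, −β₂) and corrupts the average.  The
ROI orientation is the amplitude-weighted circular mean in fold-space
(algebraically the orientation of the summed beta vectors; arithmetic
averaging of angles is ill-defined across the wrap-around).  The test
model fits the single realigned regressor cos(n(θ − φ)) on the two
held-out runs; its beta, averaged over ROI voxels (unweighted) and
runs, is the iteration's statistic, and the symmetry magnitude is the
mean over the four iterations.  For visualisation, held-out trials
are binned by θ − φ into twelve 30° bins (exactly two trials per bin
per run on the 24-direction design); aligned bins are those centred
on multiples of 360/n.

A subtlety the tests quantify: chaining correlates consecutive trial
directions, and HRF overlap between consecutive trials plus
imagination-duration jitter leaves a small session-specific leakage
of a planted n-fold signal into other periodicities (0.2–7 % of the
own-fold beta across session seeds, ≈ 3 % in expectation, sign mostly
positive because the held-out regressor is adapted on training data
from the same session).  The orthogonality of cos(6θ) and cos(4θ) on
24 equally spaced directions therefore holds in expectation over
session randomisations, not exactly per session; the acceptance check
averages the leakage fraction over six independent session designs.
In cohort simulations the per-participant randomisation of trial
order, jitter and targets (the shared element across participants is
only the 24-chord combination) decorrelates the leakage across
subjects, and per-subject measurement noise dominates its sign.

## Circular statistics

Grid orientations live on a 360/n-periodic domain, so samples are
projected into fold-space (angles multiplied by n) before computing
the resultant or testing uniformity — without the projection the
Rayleigh test is invalid on such data.  The Rayleigh p-value uses the
standard small-sample approximation
`p = exp(√(1 + 4n + 4(n² − Rw²)) − (1 + 2n))` with `Rw = nR`; the
suite verifies calibration (rejection rate 0.05 ± 0.01 under
uniformity at n = 19 over 10⁴ samples) and agreement with a
Monte-Carlo null within 10 % over p ∈ [0.01, 0.5].  The von Mises
sampler used for clustered phases is the Best–Fisher rejection
algorithm, checked against its resultant expectation I₁(κ)/I₀(κ).

## Path-integration scoring

Reported distances are corrected by standardization-walk factors
C_f = d_true / d̄_response (5 m and 10 m walks, two administrations
averaged); reports up to 7.5 m use the 5 m factor, larger ones the
10 m factor, and the sub-4 m tail (possible in synthetic data) also
uses the 5 m factor.  Each stop's corrected distance and pointing
direction imply a presumed start `stop + d · (cos Ori, sin Ori)`; the
per-stop error is the distance between successive presumed starts
(the true start before the first stop), so a perfect integrator
scores zero at every stop and each path segment is scored
independently of cumulative drift.  Performance is the reciprocal of
the mean error, with an explicit infinite-performance flag at zero
error.  Orientations are in the court's planar frame; compass
readings must be converted upstream.  The eight bundled paths are a
synthetic stand-in laid out along the lines of the 10.97 m × 11.88 m
half-court with stop distances in the task's 4–14 m range — they have
the experimental structure but are not the experiment's paths.

The key analytical identity — a shared multiplicative distance bias
cancels exactly through the correction factors, regardless of which
factor branch each report takes — is tested both algebraically and
through the simulator.

## Group inference

One-sample tests of symmetry magnitudes are one-tailed (positive
modulation is the hypothesis); everything else is two-tailed.  A
Shapiro–Wilk gate at α = 0.05 selects the t test or the Wilcoxon
signed-rank; the signed-rank uses Pratt handling of zeros and average
ranks for ties with a tie-corrected normal approximation (frozen
reference values from an independent statistical library are in the
tests), and its effect size is r = |z|/√n.  Group comparisons use the
pooled-variance t test or the rank-sum test, with Levene's test
reported alongside.  Within-group periodicity tests are
Bonferroni-corrected across the five tested symmetries (α = 0.01);
Rayleigh tests on orientations use α = 0.01.  Correlations are
Pearson; a supplied covariate is partialled out by residualising both
variables (p on n − 3 degrees of freedom).  The group-by-covariate
interaction is the t test of the product term in
`y ~ covariate * group`.

`simulate_study()` assembles the full synthetic cohort: a
sighted-like group (6-fold, uniform orientations) versus a blind-like
group (4-fold, orientations von Mises-clustered 30° off the vertical
6–12 axis, κ = 8), group-specific path-integration behaviour
(distance gain 0.95 vs 0.85, angular SD 12° vs 20°), questionnaire
items whose route/survey means separate the groups while the
navigation-confidence items (including the shared q5s item) do not,
and a parietal activity scalar that co-varies with 4-fold magnitude
only in the blind-like group (planted correlation ≈ 0.55).
`build_report()` runs the whole battery and summarises the
qualitative pattern as named flags.

## Problem sizes and numerical choices

The bundled studies use: 50 subjects for phase recovery; 400
independent groups of 19 null subjects (12 voxels each — the group
test statistic is invariant to ROI size) for type-I calibration; 10⁴
samples for Rayleigh calibration; 19 + 19 subjects at 110 voxels for
the cohort emulation.  Tolerances: noiseless closed-loop recovery is
asserted to 1e-6° (measured ≈ 1e-14); collinearity in the left/right
judgment errors out below 1e-9 of the squared radius (unreachable for
admissible targets); the pseudo-inverse truncates singular values
below 1e-10 of the largest.  All generators take explicit integer
seeds and restore the caller's RNG state.

## Known limitations

The estimator's averaging-of-run-betas differs from a single pooled
multi-run GLM when designs are unbalanced; the two coincide here
because every run covers all 24 directions.  The Wilcoxon effect-size
convention (r = |z|/√n) is one of several in use.  The Rayleigh
approximation is slightly conservative at very small n.  The leakage
analysis above implies that with extremely clean data even a true
n-fold signal produces small positive cross-fold statistics; at
realistic noise this is far below detection, but it is a property of
adapted cross-validated designs worth knowing about.
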