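---
title: "Scoring gait stability and fatigue recovery with gaitstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gait stability and fatigue recovery with gaitstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Falls, slips and trips are the dominant accident class on construction
sites, and their immediate precursor is a loss of body stability while
walking. Two factors interact to erode stability: accumulated physical
fatigue, and the walking surface itself (obstacles, wet or oily floors).
`gaitstab` quantifies that interaction from a single waist-worn tri-axial
accelerometer (sampled at 128 Hz, at the body's centre of mass), using
dynamic time warping (DTW) against each person's own unfatigued gait as the
stability score, and a logarithmic trendline through the post-hazard scores
as the recovery-time estimate.

The experimental design the package models is a 6 x 4 factorial: fatigue
levels 0–5, where level *k* means the worker performed *k* x 10% of their
individual Harvard-step-test failure count before the walk, crossed with
four walkway conditions — non-obstacle (A), obstacle (B), water (C) and
oil (D) — each containing a hazard zone partway along the walk.

## The scoring model

Every trial is reduced to a scalar series: the signal vector magnitude
(SVM) `sqrt(ax^2 + ay^2 + az^2)`, which is invariant to sensor orientation.
The SVM series is cleaned with a Hampel filter (window 11 samples,
threshold 3 scaled MADs; the median replaces flagged samples), then
segmented into gait cycles: local maxima of a 0.25 s moving-average
smoothed SVM, gated at a topographic prominence of 0.5 x the series IQR and
a minimum spacing of 0.4 s, define step peaks; consecutive peak-to-peak
intervals are the cycles. Prominence is expressed relative to the IQR so
segmentation is invariant to amplitude scale; all intervals in the package
are 0-based and half-open.

The **reference gait** is extracted from the participant's fatigue-level-0,
non-obstacle trial as the *medoid* cycle — the cycle minimising total DTW
distance to the trial's other cycles. When the trial records a hazard
window, only the cycles before it enter the medoid pool: that stretch is
plain undisturbed walking, so neither the hazard response nor the
post-hazard recovery transient can leak into the reference. The medoid (rather than a mean
template) stays inside DTW's own metric, needs no resampling of
unequal-length cycles, and is robust to a few perturbed cycles, whose total
distance is inflated.

DTW between the reference `C` (length I) and a test cycle `T` (length J)
uses squared Euclidean local distance `d(i,j) = (C_i - T_j)^2`, the
cumulative-cost recurrence

    g(i,j) = d(i,j) + min(g(i-1,j), g(i,j-1), g(i-1,j-1)),

no global warping window, and no path-length normalisation: the reported
stability score is the raw minimal cumulative cost `g(I,J)`, and the warp
path (length Q, `max(I,J) <= Q <= I+J-1`) is recovered by backtracking with
a deterministic tie-break (diagonal, then vertical, then horizontal). DTW
runs on the scalar SVM series, not per axis. A higher score means the cycle
deviates more from the person's own unfatigued gait, i.e. lower stability.
The dynamic program is verified in the test suite against an exhaustive
enumeration of all valid warp paths on short sequences.

**Hazard-zone stability** for a trial is the mean per-cycle DTW over the
cycles whose sample interval overlaps a hazard window (any non-empty
intersection of half-open intervals — partial overlap counts, because the
perturbation affects partially overlapping cycles too). Condition cells
(environment x level) average trials with equal weight.

## Recovery time

Recovery is built from three constructs per trial:

* the **baseline** ("before-hazard average"): mean per-cycle DTW strictly
  before the hazard (at least 3 cycles);
* the **peak point**: the hazard-zone cycle with maximal DTW (earliest on
  ties);
* the **trendline** `y = -a ln(x) + b`, least-squares fitted to the
  post-peak scores with `x = 1, 2, ...` the cycle offset after the peak.

The **meeting point** is the analytic intersection of the trendline with
the baseline, `x* = exp((b - baseline)/a)`, and `x*` is the recovery time
in cycles after the peak (`cycles_to_seconds()` converts via the trial's
mean cycle duration). We use cycle offsets as the x unit because the
stability score itself is per-cycle; an `a <= 0` fit (no decreasing trend)
is a non-converged recovery and is excluded — and counted — by the
summaries rather than aborting a run. The fit window runs from the first
post-peak cycle to the end of the trial (capped at the next hazard in
two-hazard trials) and needs at least 4 points.

## The synthetic cohort generator

No accelerometer recordings are distributed with the study design the
package targets, so `gaitstab` ships a seeded generator whose outputs carry
full ground truth (cycle boundaries, hazard windows, injected magnitudes,
decay coefficients). Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 72 | cohort size |
| levels x environments | 6 x 4 | the full factorial (24 trials/worker) |
| `sampling_rate` | 128 Hz | IMU rate |
| `cycles_per_trial` | 30 | walk length in gait cycles |
| failure counts | trunc. normal (120, 30, min 40) | step-test steps to failure |
| step frequency | normal (1.8, 0.12) steps/s | walking cadence |
| base amplitude | normal (3.0, 0.3) m/s² | vertical SVM excursion |
| sensor noise | 0.05 m/s² | white, per axis |
| timing / amplitude jitter | 2% / 5% per cycle | gait variability at level 0 |
| fatigue multiplier | 1x at level 0 → 3x at level 5, linear | scales both jitters |
| hazard | 2 whole cycles at 40% of the walk | unit-energy Hann-windowed sway burst per cycle |

Each cycle is a fixed 3-harmonic cosine template of the step frequency
(symmetric about the step peak, so smoothing does not displace the ground
truth boundary), placed on the vertical axis over gravity, with smaller
even-symmetric components on the horizontal axes. The failure-count
distribution and the linear fatigue-multiplier mechanism are package design
choices — the study protocol defines the levels as percentages of an
individual failure count but publishes neither the count distribution nor a
variability mechanism, only outcomes.

**Calibration.** The hazard burst magnitude per (environment, level) is not
hand-tuned: `calibrate_hazard_magnitude()` bisects on the scale until the
mean hazard-zone DTW of a pilot simulation (60 replicates, each scored by
the full pipeline against its participant's own reference) matches the
condition's target mean to 1%. The pilot uses common random numbers — the
same replicate seeds at every bisection step — so the pilot mean is a
deterministic, monotone function of the scale. The packaged presets carry
magnitudes calibrated this way against the published condition means
(`scripts/calibrate.R` regenerates them); the non-obstacle level-4 target
is not part of the published series and is filled with the midpoint of its
neighbours (16.9), configurable like every other target.

**Recovery injection.** After the hazard, cycle *k* (counting from 1)
receives a burst whose energy follows `e(k) = max(0, b - a ln k)` with
`b` set to the condition's hazard DTW target and `a = b / ln(K)`, so the
injected excess reaches zero at `K` cycles after the peak. `K` rises with
fatigue level (15, 20, 26, 33, 41, 50 cycles for levels 0–5). Because the
measured DTW excess is approximately proportional to injected burst energy,
the measured decay is again affine in `ln k`, and the fitted meeting point
lands near `K` regardless of the noise floor — the generator therefore
produces recovery times that increase with fatigue level by construction,
which is the qualitative behaviour the recovery analysis is tested against.
In practice DTW's warping absorbs proportionally more of a weak burst than
of a strong one, so fitted recovery times compress toward smaller values
than the nominal `K`; the ordering across levels is preserved, and that
ordering — not the nominal `K` — is the tested claim.

## What the generator does and does not emulate

It emulates: quasi-periodic waist-level acceleration with a realistic SVM
peak per step; fatigue-dependent timing and amplitude variability; a
transient hazard response calibrated to published condition means;
logarithmic post-hazard recovery toward the pre-hazard floor; and the
one-or-two-hazard walkway layouts. It does not emulate: musculoskeletal
dynamics, foot-strike asymmetry, turning, sensor drift or orientation
change, or inter-cycle correlation of gait variability. Passing the
package's end-to-end checks therefore demonstrates that the *pipeline*
recovers known ground truth under controlled, study-shaped conditions — it
does not validate the physiological claims on real workers.

## Numerical and testing choices

* Bisection tolerance 1% (pilot means); re-simulated cohort means are
  checked to 10%, reflecting Monte-Carlo spread at 72 participants x 10
  seeds.
* The end-to-end ordering checks (stability non-decreasing with level;
  recovery time longer at level 5 than level 0, in every environment) run
  16 participants x 10 seeds per condition and compare levels {0, 2, 4, 5},
  whose adjacent target gaps (>= 1.3 DTW) are an order of magnitude above
  the Monte-Carlo standard error at that size; resolving the 0.3-DTW gaps
  between some adjacent published levels would need cohorts far beyond a
  test suite's budget.
* Degenerate inputs fail loudly and specifically: empty series, non-finite
  samples (with the offending index), windows larger than the series, flat
  series with no detectable gait, hazard windows touching the first or last
  cycle, fewer than 3 pre-hazard cycles, fewer than 4 post-peak points.
* Determinism: every stochastic output is a pure function of its seed; the
  cohort generator derives distinct per-trial seeds from the cohort seed,
  and RNG state is always restored on exit.

## Known limitations

* The gait detector is a general prominence-gated peak picker; pathological
  gaits (shuffling, double peaks per step) would need retuned smoothing and
  prominence parameters.
* Published per-environment Pearson correlations and printed meeting-point
  x-values in this literature are frequently computed on raw trials that
  are not deposited; `pearson_r()` and `recovery_time()` implement the
  definitions and make no attempt to force agreement with any particular
  printed value that cannot be recomputed from printed inputs.
* Recovery-time estimates are analytic extrapolations of a log trendline;
  for trials whose fitted slope is near zero the implied time is
  effectively unbounded and should be read as "did not recover within the
  observation window", not as a literal duration.
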