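---
title: "Instrumented chair-stand and TUG analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrumented chair-stand and TUG analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuperf)
```

## What the package models

Two standard clinical tests of physical performance, performed while the
subject wears an inertial measurement unit (IMU) at the fifth lumbar
vertebra:

* **30-s Chair Stand (30CST)** — stand up from a chair and sit down again,
  repeatedly, for 30 seconds. The standard clinical outcome is the number
  of completed repetitions.
* **Timed Up and Go (TUG)** — rise from a chair, walk three metres, make a
  180° turn, walk back and sit down. The standard outcome is the stopwatch
  duration.

The sensor yields triaxial acceleration (antero-posterior, medio-lateral,
vertical; m/s², ±2 g range) and angular velocity (°/s, ±250 °/s range) at
100 Hz. From these the package segments the tests into subphases, computes
movement-quality features, and asks a concrete question: do the
instrumented features discriminate *High* from *Very High* Functional
Status — a median split of the Late-Life Function and Disability
Instrument (LLFDI) function score (0–100, higher is better) — as well as
the standard clinical outcomes do?

The analysis chain is: median dichotomization of the LLFDI; log transform
of the jerk scores and z-scoring of all instrumented features; a
report-only restricted-cubic-spline linearity check; iterative
variance-inflation-factor (VIF) pruning at threshold 10; a liberal
univariable logistic screen (Wald p ≤ 0.15); stepwise backward
multivariable logistic regression (retain at p ≤ 0.05); AUC comparison of
the standard, instrumented and combined models with the DeLong test; and
Harrell-style bootstrap optimism correction with full reselection inside
every resample.

## Feature definitions

For a signal segment $s_1,\dots,s_N$ with mean $m$ sampled at $f_s$:

* **RMS** (intensity): $\sqrt{\tfrac1N \sum_i (s_i - m)^2}$ — the
  standard deviation with $1/N$ normalization. The mean removal makes it
  insensitive to the static gravity component, so gravity is deliberately
  not subtracted beforehand.
* **Normalized jerk score** (smoothness, units m for acceleration input):
  $\sqrt{\tfrac{T^5}{2}\int \dot a^2\,dt}$ over the subphase of duration
  $T$. The square root is required for the score to carry units of
  metres and to scale linearly with acceleration amplitude.
* **Angular jerk score** (dimensionless):
  $\sqrt{\tfrac{T^5}{2\,TA^2}\int \ddot\omega^2\,dt}$ with turning angle
  $TA = \int\omega\,dt$ — a pure shape functional, invariant to both the
  amplitude and the duration of the turn.
* **Turn kinematics**: $TA$ by the trapezoid rule; mean yaw velocity as
  the arithmetic sample mean; maximum yaw velocity reported as a
  magnitude, irrespective of turn direction.

Derivatives use central differences (one-sided at segment ends; for the
second derivative the end values replicate the nearest interior point)
and integrals the trapezoid rule — second-order accurate with no further
dependencies. On closed-form signals at 100 Hz the observed error is
below 1%.

The canonical registries hold 21 chair-stand features (repetition count;
mean and SD of each transition type's duration; acceleration jerk scores
per axis; acceleration RMS per axis; medio-lateral and vertical gyroscope
RMS — per transition type) and 28 TUG features (total and four subphase
durations; walking and turning step counts; acceleration RMS in
sit-to-walk, walk and turn-to-sit; acceleration jerk scores in
sit-to-walk and turn-to-sit; angular jerk score, mean and maximum yaw
velocity in the 180° turn and the turning part of the turn-to-sit). The
published feature families do not multiply out to an unambiguous
enumeration; this registry is one consistent reading that reaches the
printed counts, and it is exposed via `feature_registry()` so alternates
can be swapped.

Features undefined for a subject (a missing subphase, a single
repetition) are missing values, never silent zeros; subjects with missing
modelled features are dropped listwise before modelling.

## Segmentation

Postural transitions are detected on the rectified medio-lateral angular
velocity smoothed by a zero-phase low-pass (2nd-order Butterworth run
forward and backward, cutoff 2 Hz): local envelope maxima above 15 °/s
are transition candidates, and each accepted candidate spans the region
where the envelope stays above 10% of its peak, bounded by the envelope
valleys shared with neighbouring candidates. Two refinements make this
robust for back-to-back movements:

* *Lobe clustering.* A biphasic trunk rotation produces two envelope
  lobes. Maxima closer than 0.35 s, or whose shared valley stays above
  15% of the lower lobe, are treated as one movement. Between distinct
  movements the envelope falls essentially to the noise floor, so the
  valley rule separates them.
* *Sign disambiguation.* The two lobes of one biphasic movement carry
  opposite signs of the filtered signal, whereas the facing lobes of two
  successive opposite transitions carry the same sign; equal-signed
  neighbours are therefore never clustered. This resolves the ambiguous
  regime where short pauses (< 0.3 s) between standing and sitting leave
  the smoothed envelope elevated.

Direction (sit-to-stand vs stand-to-sit) comes from the sign of the
low-pass-filtered antero-posterior acceleration at the envelope peak: the
trunk accelerates forward when rising, backward when sitting down.

Turns are detected the same way on the vertical gyroscope, qualified by
an enclosed yaw integral of at least 120°; the first qualifying burst is
the 180° turn, the second the turning part of the turn-to-sit. Steps are
peaks of the 0.7–3 Hz band-passed vertical acceleration above an adaptive
threshold (40% of the segment's 95th absolute percentile — invariant to
amplitude scaling), separated by at least 0.3 s.

Intervals are half-open `[start, end)` seconds; conversion to sample
indices floors the start and ceils the end. Recordings shorter than 5 s
(30CST) or 8 s (TUG) are rejected with a structured error. All filter
and threshold settings live in `seg_config()`; the defaults were chosen
for 100 Hz human-movement signals and validated only against the
synthetic generator — the original detection algorithms for real
smartphone data are not published in reproducible detail, so this module
is a documented surrogate.

## The synthetic cohort generator

No instrumented recordings from the original study population are
deposited, so the generator is the package's study bench. It emulates
the statistical structure the analysis assumes, not biomechanics:

* Each subject has latent movement parameters (transition durations and
  their variability, pauses, per-axis movement amplitudes, trunk tilt,
  walking cadence and intensity, walk time, two turn peak velocities)
  drawn from the normal populations tabled in `population_defaults()`,
  truncated at physical floors.
* A near-binary functional-status latent $g = 0.9\,\mathrm{Bernoulli}(\tfrac12)
  + 0.1\,U(0,1)$ shifts parameter means linearly: an injected effect $d$
  moves the conditional mean by $(g - \tfrac12)\,d\,\sigma$, so subjects
  at latent 1 and 0 differ by exactly $d\sigma$ and the realized
  dichotomized group difference is close to $0.9\,d$. The LLFDI score is
  a logistic map of $g$ onto $[44, 100]$ plus Gaussian noise (default SD
  6 points), clipped to $[0, 100]$ — matching the skewed, high-functioning
  score range such cohorts show.
* Signals are rendered from closed-form pulses: Gaussian-windowed
  sinusoids for postural transitions (smooth, finite jerk, with
  10%-of-peak crossings near the nominal edges), cadence-locked
  sinusoids for gait, and flat-top pulses with cosine ramps for turns,
  whose plateau equals the subject's peak yaw rate and whose integral is
  180° ± a small jitter. Gravity sits on the vertical axis and transfers
  partially to the antero-posterior axis through the tilt profile during
  transitions, so feature code can be exercised with and without gravity
  handling.
* *Within-subject variability is essential, not cosmetic.* Every
  transition gets per-execution amplitude jitter, each turn its own
  jittered peak and a variable mid-turn surge, and the turn before
  sitting has its own latent peak velocity. Without this, jerk scores
  are deterministic functions of duration and the two turns' kinematics
  are collinear copies, and VIF pruning removes exactly the features the
  analysis is meant to select. Real movement data decorrelates feature
  families the same way.
* The 30CST packs whole cycles (sit pause, stand up, stand pause, sit
  down); a trailing partial cycle is omitted entirely, and only complete
  sit-to-stand transitions count as repetitions. A cycle that cannot fit
  in 30 s at all is a configuration error.
* Standard clinical outcomes are emitted alongside: the assessor's
  repetition count (the true count) and the stopwatch TUG duration (truth
  plus a 0.3 s reaction offset and 0.2 s timing noise).
* One root seed governs everything; subject $i$ runs under
  `subject_seed(seed, i)`, an affine counter modulo $2^{31}-1$, so any
  subject regenerates in isolation. Identical specifications give
  byte-identical cohorts.

What passing tests on this generator do *not* show: robustness to real
sensor artefacts (drift, re-orientation, clipping from impacts), to
atypical movement strategies, or to segmentation behaviour on
populations outside the rendered parameter ranges. Signal amplitudes are
free parameters of the generator, documented here, and are not claimed
to match any particular cohort's recordings.

## Statistical pipeline: numerical choices

* The median split labels scores at or above the cohort median as Very
  High Functional Status; with ties at the median the split can be
  uneven, as in realistic score distributions.
* Logistic models are fitted by `stats::glm` — iteratively reweighted
  least squares — with deviance tolerance $10^{-8}$ and at most 100
  iterations; quasi-separation is flagged by a coefficient magnitude
  guard (|coef| > 20 on the z-score scale). Wald p-values drive both the
  screen and the stepwise deletion; the likelihood ratio is used only in
  the spline linearity check. The linearity check is report-only: no
  feature is excluded on its account.
* The restricted cubic spline uses three knots at the 0.1/0.5/0.9
  empirical quantiles, giving one nonlinear basis column, built from the
  standard truncated-power formula.
* VIF is computed as the diagonal of the inverse correlation matrix
  (equal to $1/(1-R^2_j)$ from regressing feature $j$ on the rest);
  a singular correlation matrix falls back to explicit per-feature
  regressions with perfectly collinear features flagged at infinite VIF
  and removed first. Ties break to the first feature in canonical column
  order.
* AUCs use the Mann–Whitney construction with ties counted ½, computed
  via midranks in $O(N\log N)$; variances and the test for two
  correlated AUCs use DeLong's structural components. Identical or
  rank-identical score vectors give a difference of exactly zero and
  p = 1; a degenerate variance with a nonzero difference yields a
  missing p-value rather than a fabricated one.
* Bootstrap internal validation repeats the *entire* selection (VIF
  pruning, screen, stepwise) inside each resample, scores the resample
  model on both the resample and the original data, and subtracts the
  mean optimism from the apparent AUC. Resamples containing one outcome
  class are redrawn and counted. The default is B = 1000 replicates;
  the shipped tests and the acceptance script use B = 200, at which the
  optimism estimate's Monte-Carlo error is already small relative to
  its sampling variability across cohorts.
* In the sensitivity analysis the instrumented candidate set excludes
  the sensor-derived repetition count and total TUG duration, so the
  instrumented model reflects movement quality only; the combined model
  is the instrumented survivors plus that sensor-derived standard
  measure, refitted without reselection.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at the
study scale of 160 subjects (the cohort size the analysis design
assumes), with 50-seed replications for segmentation recovery and
end-to-end structure recovery, 200 seeds for screen calibration, 400 for
DeLong null uniformity, and bootstrap validation at B = 200 over 10 null
runs — sizes that keep a full run in the minutes range on a single
core.

## Known limitations

* The generator's latent-to-signal map is low-dimensional by design;
  effect sizes injected on latent parameters attenuate at the feature
  level (duration variability is estimated from ~8–10 repetitions; turn
  peaks carry execution jitter), so end-to-end recovery of a d = 0.5
  effect is probabilistic, not certain — mirroring the modest power of a
  160-subject median-split design.
* Stepwise selection among correlated expressions of the same latent
  (e.g. the maximum and mean yaw rate of one turn) keeps whichever
  survives the Wald ordering in a given sample; which one appears in a
  final model varies across seeds, as it would across real cohorts.
* The LLFDI is modelled only as a noisy monotone readout of the
  functional latent; no item-level or domain structure is simulated.
* Optimism correction combined with variable selection is a biased
  estimator on null data: when selection on the full data keeps nothing
  the apparent AUC is exactly 0.5 while resample selections still
  overfit, so the corrected AUC dips below 0.5 by roughly the mean
  resample optimism. This is a property of the estimator itself at
  small subjects-per-candidate ratios, visible in the shipped null
  calibration check, not an implementation artefact.
* No regularized or Bayesian alternatives to stepwise selection, no
  external validation, and no calibration-curve assessment are provided.
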