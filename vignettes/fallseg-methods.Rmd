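---
title: "Detecting slipping perturbations from body-segment kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting slipping perturbations from body-segment kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallseg)
```

## The problem

A pre-impact fall detector must notice, within a few hundred milliseconds,
that a walking person has been destabilised — early enough for a protective
system (air-bag, exoskeleton) to react before impact. `fallseg` implements a
whole-body approach to this problem: the 3D linear accelerations of the
centres of mass of 15 body segments (head/neck, chest, pelvis, and both
upper arms, forearms, hands, thighs, shanks and feet) are observed while a
subject walks on a treadmill that occasionally delivers a sudden,
multidirectional slipping perturbation under one foot. The question the
package answers is twofold: *can* the transition from steady gait to a
perturbation be classified sample-by-sample, and *which segments carry the
information*, so that a practical detector needs only a few sensors?

Ten perturbation types are modelled — five directions (forward, forward
diagonal, purely sideways, backward diagonal, backward; codes combining N/S
and E/W belt movements) delivered under either the left or the right foot —
with two sessions each, giving 20 trials per subject. Each trial is a 6 s
window sampled at 100 Hz: 5 s of walking before the perturbation onset
(walking phase, 500 samples, labelled `W`) and 1 s after it (perturbation
phase, 100 samples, labelled `P`).

## The analysis pipeline

Per subject, the pipeline is:

1. **Dataset assembly.** The 20 trials are concatenated column-wise into a
   matrix `M` of 45 channels (15 segments × 3 axes) by 12 000 samples
   (`assemble_dataset()`).
2. **ICA1 — informativeness ranking.** The number `N` of retained
   independent components is chosen as the smallest principal-component
   count explaining 95 % of the variance of mean-centred `M`
   (`select_n_components()`), and a FastICA-style model is fitted
   (`fit_ica()`). Each segment's *Total Segment Weight* (TSW) is its
   cumulative absolute loading on the retained components, with each
   mixing column normalised to unit norm first, expressed as a percentage
   (`compute_tsw()`). Segments are ranked by TSW; reduced sensor sets are
   chosen bilaterally from the top of the ranking
   (`select_bilateral_subset()`), because the perturbed side is unknown in
   advance.
3. **Outer LOOCV.** Each trial in turn is held out as test set. ICA2 is
   fitted on the remaining 19 trials only, and its time-invariant unmixing
   projects both training and test data into component space. For the
   all-segments dataset ICA2 uses the `N` from ICA1; for a reduced subset
   it retains the full dataset dimension (3 × number of segments), since
   the information reduction has already been performed by the segment
   choice.
4. **Inner LOOCV.** Each of the 19 training trials in turn serves as
   validation set while a three-layer feed-forward network (tanh hidden
   and output layers, 80 hidden units by default) is trained on the other
   18 by full-batch resilient backpropagation; the epoch with minimal
   validation error provides the weights (early stopping). The trained
   network classifies the projected test trial.
5. **Detection and scoring.** Network outputs are decoded per sample into
   `W`, `P` or `NA` (uncertain) with a 0.5 activity threshold; a
   perturbation is detected when 5 consecutive samples are `P`. Each
   classified trial contributes one walking-phase outcome (TN/FP) and one
   perturbation-phase outcome (TP/FN); for true positives the detection
   time (DT) runs from the onset through the detecting sample. The
   20 × 19 = 380 outcomes per subject and segment combination are
   aggregated into sensitivity, specificity, balanced accuracy and the
   mean detection time (MDT).
6. **Comparison.** Per-type MDTs are compared across segment combinations
   by paired t-tests against the all-segments reference, and the effects
   of perturbation direction and side are assessed by a two-way
   main-effects ANOVA (`compare_combinations()`, delegating to `t.test()`
   and `aov()`).

The outer test trial never enters ICA2 fitting or network training — this
is asserted structurally in the test suite by zeroing the test trial and
checking that all trained weights are bit-identical. The ICA1 ranking is
computed once per subject from all 20 trials before the outer loop, so the
*segment choice* (not the classifier) sees all data; this mirrors the
original experimental design and is a known property, not an accident.

## Performance metrics

With `TP/FP/TN/FN` counted over all classified trials,

$$\mathrm{Sensitivity} = \frac{TP}{TP+FN},\qquad
  \mathrm{Specificity} = \frac{TN}{TN+FP},\qquad
  \mathrm{Accuracy} = \frac{\mathrm{Sens}+\mathrm{Spec}}{2}.$$

Accuracy is the *balanced* accuracy — the mean of sensitivity and
specificity. This definition reproduces exactly, to printed precision, all
four published accuracy values of the study this pipeline re-implements
(e.g. (84.8 + 98.0)/2 = 91.4), which is how it was identified; the test
suite asserts the identity. A metric whose denominator is zero is reported
as `NA`, never silently as 0.

Detection-time convention: a detection occurs at the 5th sample of a run of
consecutive `P` classifications (an `NA` breaks the run); a run straddling
the onset is assigned to the phase containing its 5th sample; DT includes
the detecting sample, `DT = (index − onset + 1)/fs`; only the first
post-onset detection defines DT. These conventions are fixed and identical
across all compared combinations, so they cancel in comparisons.

## The synthetic-data generator

No motion-capture recordings are distributed, so `generate_subject()`
produces trials with the statistical structure the analysis assumes:

- **Walking component** — per channel, two harmonics at the cadence and
  twice the cadence with segment-specific amplitudes (distal segments
  move more: feet 3.5, shanks 2.5, hands 2.0 … head 0.5 m/s² on the
  dominant axis; medio-lateral scaled by 0.6, vertical by 1.2) and
  subject-specific random phases. This is the minimal quasi-periodic
  structure that lets ICA separate gait from perturbation.
- **Perturbation transient** — an exponentially damped sinusoid
  (time constant 0.15 s, 3 Hz) starting at the onset plus a per-segment
  mechanical-chain latency (feet 0 ms, shanks/thighs 30 ms,
  pelvis/trunk/head 60 ms, arms/forearms/hands 80 ms). Its amplitude is
  4 m/s² per unit of the segment's dimensionless gain (defaults: feet 5,
  hands 4, decreasing toward proximal segments — peak transients of
  16–20 m/s² in the distal extremities, consistent with the violent distal
  accelerations seen in slip recoveries), its sign pattern follows the
  perturbation direction, and the perturbed side is weighted 1.2× against
  0.8× contralaterally.
- **Noise** — i.i.d. Gaussian, 0.1 m/s² per channel by default.
- **Walking speed** — fixed through a Froude number of 0.15
  (`froude_speed()`): with the default 0.822 m leg length, 1.10 m/s.

Determinism is a contract: one master seed per subject, per-trial seeds
derived by XOR with the trial index, so any trial set is exactly
reproducible.

What the generator does *not* emulate: step-phase-dependent perturbation
responses, inter-stride variability, marker soft-tissue artefacts,
cross-channel noise correlation, and the enormous idiosyncrasy of real
recovery reactions. Passing tests on synthetic subjects therefore
demonstrate that the *pipeline* is correct and can recover known structure
(rankings, detectability, latency ordering); they do not certify
performance on human data, and the published human-subject performance
values (e.g. MDT 351 ± 123 ms) are not reproduction targets. Synthetic
detection is in fact much easier than the real task — the scaled-down
demonstration below reaches near-perfect sensitivity and detection times of
tens of milliseconds — precisely because the transient is clean and
stereotyped.

## Numerical choices

- **Component count.** The retained dimensionality is the 95 %
  explained-variance point of the PCA spectrum — standard, monotone in the
  threshold, and reproducible. (The study's own selection procedure is in
  an appendix that is not part of the public record; this is the package's
  declared replacement.)
- **ICA.** FastICA fixed-point iteration with the log-cosh (tanh)
  contrast, deflation, convergence tolerance 1e-6, iteration cap 500, and
  5 seeded restarts scored by a negentropy proxy; the best restart is
  kept, making the fit deterministic given its seed. ICA is identifiable
  only up to component permutation and sign; the TSW statistic is exactly
  invariant to both (asserted in the tests). On full-dimension fits (the
  reduced-subset ICA2 case) the last directions can be contrast-free
  noise whose fixed-point iteration oscillates; the pipeline then keeps
  the best partially converged orthonormal rotation and warns, while
  `fit_ica()` called directly errors with diagnostics by default.
- **TSW.** Mixing-matrix columns (channel loadings) are used rather than
  unmixing rows, and each column is unit-normalised so no component
  dominates by scale; components are weighted uniformly. Ties in the
  ranking break by the canonical anatomical order.
- **Network training.** Mean squared error on ±1 one-hot targets (two
  output units, W and P) with the canonical Rprop constants
  (η⁺ = 1.2, η⁻ = 0.5, Δ₀ = 0.07, Δ_max = 50, Δ_min = 1e-6), full-batch
  gradients, weight initialisation Uniform(−0.5, 0.5)/√fan-in from a
  seeded stream, epoch cap 500, early-stopping patience 25. Two tanh
  output units make the 0.5 activity threshold and the three-way W/P/NA
  decoding natural: a sample is uncertain when neither unit is active
  enough or both are equally active.
- **Differentiation.** Three-point central differences
  (`a[t] = (p[t+1] − 2p[t] + p[t−1])·fs²`), exact for quadratics; the two
  boundary samples replicate the nearest interior value so the 600-sample
  alignment with the labels is preserved. No low-pass filter is applied
  before differentiation by default (none is known to have been used in
  the original processing); the synthetic generator emits accelerations
  directly, so the endpoint-trajectory path (`segment_com()`,
  `central_diff_accel()`) is exercised by its own tests and available for
  real marker data.
- **Anthropometry.** Segment CoM positions use the de Leva-adjusted
  longitudinal ratios (fraction of segment length from the proximal
  endpoint; male values), overridable per call.
- **Statistics.** The two-way ANOVA uses main effects only (direction,
  5 levels; side, 2 levels), matching the degrees-of-freedom pattern of
  the published analysis; the paired t-test reports a degenerate
  zero-variance difference explicitly (t = 0, p = 1 for identical
  vectors) instead of failing.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script demonstrations run a deliberately
scaled-down configuration — one synthetic subject, 20 hidden units, a
100-epoch cap with early-stopping patience 10 — chosen so the full nested double LOOCV (20 outer × 19
inner folds = 380 trained networks per combination) remains a
minutes-scale computation while exercising every stage at full structural
fidelity. Ranking-recovery checks use 10 subjects; ICA recovery uses
3 sources × 9 channels × 6 000 samples over 10 seeds. The defaults
(80 hidden units, 500 epochs) reproduce the original network capacity and
are what a real analysis should use.

## A worked example

```{r example, eval = FALSE}
library(fallseg)

# one synthetic subject, scaled-down training
params <- subject_params(seed = 42)
trials <- generate_subject(params)

cfg <- experiment_config(
  train = train_config(hidden_units = 20, max_epochs = 100),
  seed = 42)

ranking <- run_ranking(trials, cfg)
print(ranking)
subset4 <- select_bilateral_subset(ranking, 2)

report <- run_subject(trials, subset4, cfg)
print(report)
```

## Known limitations

- Per-subject models only: no pooling across subjects, mirroring the
  original design; a deployable detector would need cross-subject
  generalisation that this pipeline does not measure.
- Offline by construction: the consecutive-sample rule and the LOOCV
  protocol are analysis tools, not a streaming detector.
- The synthetic effect sizes are free parameters of the generator, not
  calibrated to any published per-segment amplitude data (none exist);
  conclusions from synthetic runs are about pipeline correctness, not
  human performance.
- ICA assumes non-Gaussian sources; on data without such structure the
  fit legitimately fails (and says so).
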