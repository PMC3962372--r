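# fallseg

Pre-impact fall detection from whole-body segment kinematics.

`fallseg` is an R package for analysts in biomechanics and wearable
sensing who want to (a) classify, sample by sample, the transition from
steady walking to a slipping perturbation using the 3D linear
accelerations of body-segment centres of mass, and (b) find out *which*
segments carry that information, so a practical detector needs only a few
sensors.

## The method

Per subject, 20 trials (2 sessions × 10 perturbation types, five per
foot) are windowed from 5 s before to 1 s after the perturbation onset at
100 Hz (600 samples: 500 walking-phase, 100 perturbation-phase) and
concatenated into a 45 × 12 000 matrix (15 segments × 3 axes). The
pipeline then runs:

- **ICA1** on the full matrix: the retained component count *N* is the
  95 % explained-variance point of the PCA spectrum; a FastICA-style fit
  (tanh contrast, deflation, seeded restarts) yields the mixing matrix,
  from which each segment's **Total Segment Weight** — its cumulative
  absolute loading on the retained components, in percent — ranks the
  segments by informativeness. Reduced sensor sets are chosen bilaterally
  from the top of the ranking.
- **Nested leave-one-out cross-validation**: each trial is held out in
  turn (outer loop); **ICA2** is fitted on the 19 training trials and its
  time-invariant unmixing projects training and test data; each training
  trial then serves once as validation set (inner loop) for a three-layer
  tanh network (80 hidden units) trained by full-batch resilient
  backpropagation with early stopping, which classifies the test trial.
- **Detection rule**: outputs are decoded to W / P / NA with a 0.5
  activity threshold; five consecutive `P` samples constitute a
  detection. Each classified trial yields a walking-phase outcome (TN/FP)
  and a perturbation-phase outcome (TP/FN); detection time (DT) runs from
  the onset through the detecting sample. Over the 380 outcomes per
  subject and segment combination:

  Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
  Accuracy = (Sensitivity+Specificity)/2, MDT = mean ± sd of the TP
  detection times.
- **Comparison** across segment combinations: paired t-tests of MDT
  against the all-segments reference and a two-way main-effects ANOVA
  (direction × side).

Because no motion-capture data are distributed, the package includes a
first-class synthetic-gait generator (quasi-periodic walking harmonics,
perturbation-locked damped transients with segment-dependent amplitude
and latency, Gaussian noise, walking speed fixed by a Froude number of
0.15) that reproduces the statistical structure the analysis assumes. See
`vignettes/fallseg-methods.Rmd` for the model, every tunable parameter
and the design decisions.

## A worked example

```r
library(fallseg)

params <- subject_params(seed = 42)       # leg 0.822 m -> 1.10 m/s at Fr 0.15
trials <- generate_subject(params)        # 20 labelled 6-s trials

cfg <- experiment_config(
  train = train_config(hidden_units = 20, max_epochs = 100),
  seed = 42)

ranking <- run_ranking(trials, cfg)       # ICA1 + TSW
print(ranking)
#> segment_ranking (6 ICs retained):
#>   RF    15.20 %
#>   LF    14.28 %
#>   LS     9.53 %
#>   LH     8.60 %
#>   RS     8.55 %
#>   RH     8.12 %
#>   LFA    5.49 %
#>   ...
#>   HN     1.88 %
```

The distal lower limb dominates: the feet, hit first and hardest by the
belt movement, top the ranking by a wide margin, with shanks and hands
close behind and the trunk and head carrying the least information.
`select_bilateral_subset(ranking, 2)` expands the top two ranked groups
bilaterally — here `c("LS", "RS", "LF", "RF")` — and the nested LOOCV
evaluates that four-segment sensor set:

```r
report <- run_subject(trials, select_bilateral_subset(ranking, 2), cfg)
print(report)
#> performance_report: TP 380  FP 0  TN 380  FN 0
#>   sensitivity 1.000  specificity 1.000  accuracy 1.000
#>   MDT 61 +/- 6 ms
```

On clean synthetic data, detection is near-perfect and fast: the
perturbation transient starts in the feet at the onset, so the 5-sample
rule fires roughly 50–60 ms later. Synthetic runs demonstrate pipeline
correctness (ranking recovery, detectability, latency ordering), not
human-subject performance.

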