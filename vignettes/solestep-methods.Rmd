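---
title: "Counting steps from a sole-embedded IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting steps from a sole-embedded IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`solestep` implements a step-counting pipeline for a six-axis IMU (200 Hz,
±16 g, ±2000 °/s) embedded under the heel of a running shoe. A step is
defined by its *foot-flat* phase — the part of stance in which the sole is
stationary relative to the ground, operationalized as the sole angle staying
strictly below 3°. The pipeline has two stages:

1. a windowed many-to-one LSTM classifier that maps a short history of
   inertial samples to the probability that the foot is flat at the window's
   final sample, and
2. a refractory-period counter: each 0→1 transition of the thresholded
   foot-flat stream registers one step, and any further onset within the
   *rest delay* (RD) after a registered onset is suppressed, preventing
   double counts within a single stance.

Because the study population that motivates the defaults is not public, the
package ships a synthetic multi-activity cohort generator that reproduces
the statistical structure that matters to the pipeline, so the whole method
can be exercised and validated end to end.

## The classifier

Input windows of `round(input_window_ms * fs / 1000)` samples are cut from
the retained channels, one window per labeled sample, the label being the
foot status of the window's *final* sample — prediction is causal ("anterior
data at the considered moment"). The default architecture is the optimized
one: two stacked LSTM layers of 32 units (intermediate layers emit full
sequences, the last its final state), dropout 0.2 on the final state, no
intermediate dense layer, and one sigmoid output unit giving P(foot flat).
Gates use sigmoid activations; the cell input/state activation is
configurable (`tanh`, `sigmoid`, `relu`; default `tanh`).

Training minimizes binary cross-entropy with Adam (learning rate $10^{-2}$,
batch 1024 by default) and the three stopping rules: 100 epochs maximum, 10
epochs of patience on the validation loss, and a 5-minute wall-clock budget,
whichever hits first; the best-validation weights are restored. The
numerical core is implemented in C++ (RcppArmadillo): full backpropagation
through time, Glorot-uniform initialization with forget-gate biases at 1,
and a global gradient-norm clip of 10 (a guard rail mainly for the `relu`
cell activation explored during tuning; it is configurable). Probabilities
are thresholded at 0.5 (`>=`), exposed as `decision_threshold`.

Two deliberate reproductions of the study design are worth flagging. First,
the held-out fold serves as *both* validation (early stopping) and test set,
which entangles model selection with evaluation; `evaluate_split()` and
`cross_validate()` reproduce this. A nested split can be emulated by passing
a different validation fold explicitly through the lower-level functions.
Second, training windows may be thinned with `train_stride` (default 4 in
the evaluation helpers) — this only thins gradient examples; prediction is
always per-sample.

## Channel selection

Eight candidate channels (three acceleration axes, three gyroscope axes, two
norms) are ranked by Pearson correlation with the binary foot status, pooled
over the cohort with undetermined samples dropped. Channels with |r| ≥ 0.1
are retained. Selection uses the *magnitude*: with status coded 1 = flat,
the gyroscope norm is strongly *negatively* correlated (the foot is
quiescent when flat) and is exactly as informative as a positive channel;
reported calibration values are therefore |r|. On the default synthetic
cohort the retained set is `{gyro_norm, acc_norm, acc_z}`.

## Step extraction and metrics

`count_steps()` scans the stream left to right; the stream start counts as a
preceding 0, and the refractory clock starts at each *registered* onset (the
detection instant). The rest delay is selected by sweeping 25–1000 ms in
25 ms steps (40 grid points) and minimizing the mean step-count error, ties
broken toward the smaller delay. Two errors are reported:

- `MAPE_DL` — |#flat-labeled samples predicted − observed| / observed,
  computed on labeled (determined) samples only. Counting *samples* rather
  than flat *phases* is a documented choice; the phase-count variant can be
  swapped in at one isolated call site.
- `MAPE_G` — |steps predicted − steps observed| / steps observed, the
  headline step-count error.

One deviation from a literal reading of the labeled-stream convention: the
stream used for *counting* covers every IMU sample in the annotated span,
including samples whose video label is undetermined. Occlusion gaps average
half a second while a running foot-flat phase lasts ~0.18 s; a counting
stream with gaps structurally swallows whole steps (a ~5% undercount that no
rest delay can repair), and the deployed counter has no video and hence no
gaps. Label metrics (`MAPE_DL`) still exclude undetermined samples.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 21 subjects, each
completing a multi-activity track of about 191 steps (40 walking at three
speeds, 40 running, stomping / high knees / butt kicks in variable counts,
11 stair-descent steps, 10 walking transition steps, standing pauses), at
200 Hz with a 60 fps annotation stream and ~9.7% of frames relabeled
undetermined in contiguous occlusion runs (mean 0.5 s). Each recording opens
with the synchronization prelude: three strong heel strikes 0.5 s apart, the
third impact defining trial time 0, which `detect_sync_strikes()` recovers
from the acceleration norm (threshold 2 g, 200 ms separation, both
configurable).

The signal model is an additive burst model, not a biomechanical simulation:
per step, a half-sine sagittal angular-rate burst during swing (peak 170–980
°/s depending on activity), zero-mean yaw and horizontal-acceleration
oscillations, a damped 40 Hz heel-strike transient just before foot-flat
onset, and a quiescent flat phase (gyro ≈ 0, acceleration ≈ 1 g). The foot
pitch angle follows a half-sine per swing, plus moving-average-filtered
jitter (sd 0.3°) — smoothed because white noise chatters unphysically at the
3° threshold during slow swings. Heterogeneity enters at three levels:
lognormal per-subject cadence (sd 0.07) and amplitude (sd 0.15) multipliers,
uniform per-subject sensor noise (0.02–0.05 g, 1–3 °/s), and lognormal
per-step amplitude jitter (sd 0.25).

Two structural features were calibrated once against the channel/foot-status
correlation structure the pipeline is meant to face (|r| ≈ 0.64 for the
gyroscope norm, 0.41 for the acceleration norm, 0.16 for vertical
acceleration, every individual gyroscope axis below 0.1) and then frozen:

- the per-activity amplitude table (`activity_params()`), whose spread
  across activities and subjects sets how far the pooled correlations fall
  below their single-activity values;
- the per-subject sensor *mounting yaw*, spread evenly over the circle with
  jitter. Rotating the horizontal axes leaves the norms invariant but
  distributes each subject's sagittal burst across `gyro_x`/`gyro_y` with
  varying sign, so axis-level correlations cancel in the pooled cohort. This
  reproduces the empirically observed (and mechanistically unexplained)
  weakness of individual gyroscope axes without claiming a mechanism.

The first annotated sample must not begin a spurious foot-flat phase: the
track therefore opens with five walking transition steps immediately after
the prelude, and the foot rolls from the third strike into the first step
(with visible angular rate) without settling flat. Otherwise the counting
convention — stream start counts as a preceding 0 — registers the initial
stand as one phantom step per subject, a 0.5% error floor.

What the generator does *not* emulate: slopes, turns, left-foot signals,
realistic joint kinematics, drift or bias instability in the sensors, or
video-analyst idiosyncrasies beyond occlusion runs. Passing the end-to-end
criteria on this cohort therefore shows that the pipeline recovers step
counts when the label/feature structure matches its assumptions, with
margins and variability calibrated to the study; it does not certify
performance on real multi-activity recordings.

## Evaluation protocol

`make_folds()` partitions 21 subjects into 7 random folds of 3;
cross-validation is subject-wise (a leakage guard asserts train/test
disjointness at every step). The rest delay is selected once on the pooled
held-out predictions — mirroring the single study-wide RD — rather than per
fold. Aggregates are the arithmetic mean ± sd over the 7 fold values.

The package-scale evaluation (`scripts/acceptance.R`, and the heavyweight
acceptance tests) uses a single 18-train / 3-test subject split of the
21-subject cohort with training stride 4: one LSTM training run of at most
5 minutes on ~190,000 windows, chosen so the whole evaluation (simulation,
training, per-sample prediction of three subjects, 40-point RD sweep)
completes in several minutes on one CPU. The full 7-fold protocol is
available through `cross_validate()` / `run_pipeline(profile = "full")` at
roughly seven times that cost.

## Hyperparameter search

`search_space()` realizes the 9-parameter design space (3,150,000
combinations). The printed space gives only ranges and counts, so the grid
points are explicit configuration: units {16, 32, 64, 96, 128} (the grid
must contain the optimized value 32), layers 1–3, dense layer on/off with
{8, 22, 36, 50, 64} units, windows 25–250 ms by 25, dropout 0.1–0.5 by 0.1,
three activations, 20 log-spaced learning rates in [10⁻⁴, 10⁻²], and batch
sizes {64, 128, 192, 256, 512, 1024, 2048}.

`two_stage_search()` spends 25% of its trial budget on uniform random
exploration and 75% on local refinement of the incumbent best. The local
stage is stochastic coordinate descent — one parameter at a time stepped to
an adjacent grid value, an improving direction pursued until exhausted —
interleaved with exploratory jumps whose probability and magnitude shrink
with a temperature decaying linearly from 1 to 0.2. A simpler kernel that
perturbed *every* parameter to an adjacent value with probability equal to
the temperature was implemented first and discarded: it recovered a known
separable optimum in 0 of 20 seeded runs at a 50-trial budget, because
multi-parameter adjacent steps cannot descend the ~10–15 grid steps that
separate a random start from the optimum; the coordinate-descent kernel
recovers it in 20 of 20. Trials train on a random 25% subsample of the
training windows under the standard stopping rules; windows are pre-built at
the space's maximum length and truncated to each trial's window (keeping the
most recent samples), so the search never re-cuts windows.

## Numerical conventions and degenerate inputs

- Angle exactly at the 3° threshold → *not* flat (strict inequality).
- Probability exactly at the decision threshold → flat (`>=`).
- RD sweep ties → smaller rest delay.
- Zero-variance channels: correlation reported as not computable (excluded
  from selection, with a warning); normalizer sd clamped to 1.
- Undetermined-only recordings, empty annotation tables, too-short windows,
  non-monotone time, out-of-range sensor values → immediate errors naming
  the offending quantity.
- All randomness flows through explicit seeds (`withr::with_seed` in R, a
  seeded Mersenne twister in C++); identical seeds give bit-identical
  simulations and training histories.
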