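---
title: "Methods: gait inference and intention recognition from thigh sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait inference and intention recognition from thigh sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitinfer)
```

## The problem

After a trans-femoral (above-knee) amputation the thigh remains under the
user's control while the shank and foot are gone. During walking-related
activities the thigh and shank angles of a healthy leg are strongly — but
nonlinearly — coupled, so a robotic prosthesis can, in principle, infer
what the missing shank should be doing from what the thighs are doing.
Two things cannot be inferred from thigh motion alone: the intention to
stand up and to sit down, both of which begin with the shanks still. For
those, surface EMG on the thigh muscles provides a voluntary trigger.

`gaitinfer` implements this control stack end to end:

1. **Signal path** — read tab-separated wearable recordings (int16
   accelerometer/gyroscope counts, uint8 EMG), scale them to $[-1, 1]$,
   and derive sagittal-plane segment angles;
2. **Gait inference** — a single-layer LSTM maps the four thigh features
   (left/right angle and angular speed) to both shank angles, frame by
   frame, strictly causally;
3. **Activity and intention recognition** — three low-latency
   context-window classifiers with Gaussian-mixture emissions;
4. **Controller** — a five-state machine (sitting, standing-up, standing,
   moving, sitting-down) that gates gait inference and intention handling;
5. **Synthetic data** — a seeded generator that emulates the coupled
   kinematics, sensor physics and EMG bursts, with ground truth;
6. **Evaluation** — leave-one-subject-out (LOSO) cross-validation with
   degree errors (overall, per activity, per gait phase, around activity
   transitions), precision/recall/F1 and detection latency.

## Angle estimation

Storage scaling is fixed by the sensor formats: inertial channels divide
by $2^{15}$; EMG counts map by $(v - 127.5)/127.5$, midpoint-centered so
fluctuations keep their sign. Physical units are recovered with the
nominal sensitivities (accelerometer $\pm 2$ g at 16384 LSB/g, gyroscope
$\pm 2000^\circ$/s at 16.4 LSB/(°/s)).

Each segment's start angle comes from the gravity direction in the
accelerometer,
$$\theta_{\mathrm{start}} = \arctan\!\frac{T_y}{\sqrt{T_x^2 + T_z^2}},$$
and the angle series from rectangular integration of the sagittal
gyroscope rate, $\theta(t) = \theta_{\mathrm{start}} + \sum \omega / f_s$.
Integration is cumulative-sum rectangular — the simplest scheme consistent
with streaming — and all filters are causal (trailing windows) because the
controller must act on the newest frame with no lookahead.

**Drift filter placement.** The 100-sample trailing mean used for
bias-drift suppression spans about 1.8 s at the nominal 56.35 Hz — longer
than a full gait cycle. Applied to the gyroscope before integration it
would therefore attenuate the gait-frequency rotation itself (a trailing
mean commutes with integration, and a 1.1 s period inside a 1.8 s window
nearly cancels), destroying the very signal the model needs. The filter
is therefore applied on the accelerometer path (start-angle estimation
and the posture features), and the gyroscope is integrated unfiltered by
default (`gyro_window = 1`, configurable). The package's recovery
invariant — on noise-free synthetic data the pipeline reproduces the true
thigh angle within 2° over 30 s — holds under this placement and cannot
hold under gyroscope smoothing.

The sampling rate defaults to 56.35 Hz; it is a parameter everywhere.

## Features

Four feature sets feed the four models (all min-max scaled to $[0,1]$
with bounds fitted on the training split only and persisted with each
model, so no test-set leakage):

| model | features | window (frames) |
|---|---|---|
| gait inference | $\theta_L, \theta_R, \omega_{TL}, \omega_{TR}$ | 15 |
| standing-up intention | $v_5^L, v_5^R$ | 20 |
| sitting-down intention | $v_{10}^L, v_{10}^R, d_x, d_z$ | 20 |
| sitting/standing/moving | $T_x^L, T_x^R, T_z^L, T_z^R$ | 20 |

$v_w(t)$ is the population standard deviation of the last $w{+}1$
backward first differences of the EMG signal — an EMG burst detector that
ignores the signal level. $d_x(t)$, $d_z(t)$ are the population standard
deviations of $|T^L - T^R|$ over the last 11 frames — near zero when both
thighs hold a similar steady posture, as they do just before sitting
down. "Standard deviation" uses the divide-by-$n$ (population) convention
throughout; the sample convention differs by a fixed factor that the
min-max scaling would absorb, but mixing the two silently is the real
hazard, so one convention is used everywhere. Undefined leading frames of
windowed features are zero-filled rather than trimmed, preserving frame
alignment across feature kinds.

## Recognition: context-window classification

Each recognizer scores a class $s$ for frame $t$ by the product of
per-frame class-conditional densities over a context window of $K{+}1 =
20$ frames,
$$\hat s_t = \arg\max_s \prod_{k=0}^{K} P(v_{t-k} \mid s),$$
computed as a sum of log-densities (uniform class prior, ties broken by
fixed class order). Class-conditional densities are full-covariance
Gaussian mixtures fitted by EM with k-means initialization, covariance
ridge $10^{-6} I$, and stopping when the mean log-likelihood gains less
than $10^{-4}$ or after 200 iterations. Component counts per module:
standing-up — intention 10, sitting 1; sitting-down — intention 5, others
2; sitting/standing/moving — 1 each. Full covariances are cheap at 2–4
feature dimensions.

A window of per-frame log-density sums is a rolling sum, so a whole
recording is scored in one pass; the window grows with the prefix at
sequence start.

**Threshold calibration.** The two intention modules threshold the
log-likelihood ratio (intention score minus the best competing score).
The threshold is the smallest candidate achieving event-level precision
$\ge 0.99$ with non-zero recall on the calibration (training) subjects,
swept over the midpoints of sorted unique scores. Event semantics: a true
intention span counts as detected if any positive frame falls inside it;
each maximal positive run outside every span is one false positive. A
threshold below the minimum score would declare the entire trace positive
and trivially attain precision 1 under these semantics, which is why
candidates are interior midpoints only. If no candidate attains the
target, the module receives an infinite threshold (never fires) with a
warning. Each intention module is evaluated only in its controller
context (stand-up while sitting, sit-down while standing or moving), and
both its feature windows and its context window restart at each context
entry: a gated module buffers only frames it has seen since it was
activated, so the transition motion just before the context began cannot
leak into either the features or the score window. Training, calibration
and evaluation all use the same gating.

## Gait inference: the LSTM regressor

The cell follows the standard gate equations — forget
$f_t=\sigma(W_f[v_t,h_{t-1}]+b_f)$, input
$i_t=\sigma(W_i[v_t,h_{t-1}]+b_i)$, modulation
$\tilde c_t=\tanh(W_g[v_t,h_{t-1}]+b_g)$, state
$c_t=f_t\cdot c_{t-1}+i_t\cdot\tilde c_t$, output
$o_t=\sigma(W_o[v_t,h_{t-1}]+b_o)$, hidden $h_t=o_t\cdot\tanh(c_t)$,
emission $y_t=\tanh(W_y h_t+b_y)$ — with 50 hidden units in one layer,
four inputs and two outputs. The forward pass, backpropagation through
time and the Adam optimizer are implemented directly in matrix form; the
analytic gradients are verified against central finite differences in the
test suite, and the cell against an independent scalar-loop transcription
of the equations to $10^{-12}$.

Training minimizes the mean squared error between $y_t$ and the scaled
true shank angles over non-overlapping 15-frame chunks with the hidden
state reset per chunk (overlap is configurable). Because the emission is
a tanh, targets are mapped to $(-1,1)$ by a linear map fitted on the
training-split shank range expanded by a 10 % margin — the tanh cannot
reach its endpoints, and the margin keeps real targets away from the
saturated region; training error is minimized in scaled space and
reported in degrees. Optimizer defaults: Adam, learning rate $10^{-3}$,
at most 200 epochs, minibatches of 64 chunks shuffled from the seeded
stream, early stopping with patience 10 on one held-out training
participant (the last). The LOSO harness passes a learning rate of
$3\times10^{-3}$ and a 120-epoch cap, which converges within its budget
at the cohort sizes it runs; all of these are arguments. Training is
deterministic given the seed.

Prediction is strictly causal and stateful: `gait_predictor()` carries
$h, c$ across calls, frames can arrive one at a time, and streaming
output is bit-identical to whole-sequence output. The controller — not
the model — suppresses predictions outside the moving state, keeping the
separation of concerns.

## Controller

Five states with a fixed edge set: sitting ↔ standing only through the
stand-up/sit-down transitional states; standing ↔ moving directly; no
sitting ↔ moving edge. Stand-up intention is honored only while sitting;
sit-down intention only while standing (and it takes precedence over a
simultaneous swing). Swing onset — either thigh exceeding 20°/s for at
least 3 consecutive frames — starts gait inference; stillness — both
thighs below 5°/s for 1 s — stops it. The trigger quantities are
configurable; the persistence requirements keep single-frame noise from
toggling states. Requests without a legal edge are ignored and reported,
never acted on. A randomized 10,000-step simulation asserts the edge set
is never left.

## Synthetic data: what it emulates, what it does not

The generator produces recordings in the package's file dialect plus
ground truth. Design choices:

* **Kinematics.** The thigh follows a two-harmonic sinusoid of the
  time-warped cycle phase, warped so stance occupies 62 % of the cycle
  (38 % swing). The shank follows a nonlinear, lagged function of the
  same cycle phase: a linear-plus-quadratic map of a lag-shifted base
  wave that falls through stance and rises through swing, so the
  slope-based phase segmentation and the stance/swing timing agree. The
  thigh–shank scatter over a cycle forms a closed loop (the coupling is
  deliberately not single-valued), and the lagged, nonlinear relation is
  learnable from thigh history — which is the property the gait model
  needs, and the reason a recurrent model is the right shape for it.
* **Inter-subject variability.** Each subject draws an amplitude scale,
  coupling coefficients ($a$, $b$, lag) and smooth swing/stance shape
  deviations; the swing-phase deviation scale is twice the stance-phase
  scale (2° vs 1°), implementing as a generator assumption the
  observation that legs move more freely in swing. Per-cycle duration and
  amplitude jitter add natural stride-to-stride variance. Consequence:
  part of the held-out error is irreducible, and it concentrates in
  swing — which is exactly the qualitative pattern the evaluation is
  expected to reproduce.
* **Sensor physics.** Accelerometers read the unit-gravity projection of
  the segment angle plus white noise (0.02 g), quantized at 16384 LSB/g;
  gyroscopes read the backward-difference angle derivative plus white
  noise (1.5°/s), a constant per-channel bias (SD 0.02°/s) and a slow
  random-walk drift, quantized at 16.4 LSB/(°/s). Because the emitted
  rate is the exact backward difference, integration telescopes and the
  noise-free pipeline reproduces the truth to quantization accuracy.
* **EMG.** Uint8 noise around the midpoint whose spread follows an
  activity schedule (sitting 1.5, standing 4, moving 12 counts) with
  45-count bursts spanning each intention: the burst starts 0.3 s before
  the transitional label and lasts 0.9 s. Moving-phase EMG activity is
  deliberately non-trivial so sitting-down recognition is harder than
  standing-up recognition, as it is in real data.
* **Scripts.** Activity scripts are random walks on the legal transition
  graph (or user-supplied, validated). Static bouts last several
  seconds — long relative to the 1.8 s settling of the causal drift
  filter, as in real protocols where postures are held, so posture
  features are meaningful for most of each bout.

Not emulated: muscle-physiological EMG spectra, ground contact and impact
transients, turning, magnetometer effects, irregular sampling. Passing
tests on this generator therefore demonstrate that the pipeline's
machinery is correct and that its accuracy bounds hold under the stated
kinematic and noise model — not that the same numeric errors would be
obtained on any particular real dataset.

## Evaluation protocol

One LOSO fold per participant: train the gait model and all three
recognition modules on the remaining participants, calibrate intention
thresholds on those same training subjects, then measure on the held-out
subject. Degree error is the mean absolute difference between true and
predicted shank angles, with the sensor-derived angles as truth (that is
what a real system can measure). Reported views:

* overall and per activity (frames pooled per activity; the headline
  activity mean is the unweighted mean across activities);
* per gait phase, with phases segmented from the true shank slope
  (upward = swing, downward = stance, runs under 3 frames merged);
* around activity transitions: ±15 frames (about half a second) at each
  label change between gait-relevant activities, aggregated per ordered
  pair;
* event-level precision/recall/F1 for the intention tasks and frame-level
  metrics for sitting/standing; detection latency as onset-to-first-
  positive delay in seconds, undetected events excluded from the mean
  and counted as missed.

Fold aggregation is the unweighted mean over folds (per-user averaging).
All randomized steps take explicit seeds; the harness derives per-fold
seeds from one argument.

### Problem sizes

The packaged end-to-end runs use 6-subject cohorts of ~90 s recordings —
a size chosen so a full LOSO run (six LSTM trainings plus recognizer
fitting and calibration) completes in a few minutes on one core while
leaving several hundred gait cycles per cohort. The same harness runs
unchanged on larger cohorts or on real recordings in the supported file
format (`evaluate_cohort` on a directory loaded with `read_recording`);
expect run time to scale roughly linearly in total frames times folds.

## Numerical choices and degenerate inputs

* Rolling standard deviations center the series on its global mean before
  the sum-of-squares pass, so a constant window yields exactly zero.
* Mixture densities are evaluated in the log domain via Cholesky factors
  and log-sum-exp; covariance ridge $10^{-6}I$ after every M-step.
* Min-max scaling of a zero-range column maps to 0; application-time
  values outside the training range are clipped to $[0,1]$.
* A zero-range shank target yields a degenerate angle map with a floor on
  its half-range; the trained network then predicts the constant.
* A zero acceleration vector has no defined tilt and is an error, not a
  guess; label codes outside the vocabulary are reported by validation,
  not silently dropped.
* Ties in classification break by fixed class order; equal-slope frames
  in phase segmentation inherit the previous phase (stance at the start).

## Known limitations

* Pure gyroscope integration accumulates drift over minutes; the package
  deliberately stops at the tilt-plus-integration scheme (no quaternion
  or complementary fusion), so very long continuous recordings need
  re-anchoring by the caller.
* The recognition modules assume their controller context; run
  ungated, the stand-up module would see EMG statistics it was never
  trained on.
* Event-level calibration needs at least one positive and one negative
  event among the calibration subjects, and its smallest-passing-
  threshold rule is recall-greedy by construction.
* The LSTM is trained on 15-frame chunks but deployed with unbounded
  streaming state; the tests check streaming/batch equality and causality,
  not long-horizon state stability beyond the evaluated durations.
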