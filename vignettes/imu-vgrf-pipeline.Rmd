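---
title: "Synchronizing dual-instrument running data and predicting vGRF: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronizing dual-instrument running data and predicting vGRF: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugrf)
```

This vignette documents the models and procedures implemented in `imugrf`,
the assumptions behind them, the tunable parameters with their defaults and
rationale, what the synthetic gait generator does and does not emulate, and
the numerical design choices made where the method description left the
design open.

## 1. The measurement problem

A runner on an instrumented treadmill is recorded simultaneously by a
shank-mounted IMU (3-axis accelerometer + gyroscope, 200 Hz) and by the
treadmill's force platforms (vertical ground reaction force, vGRF, 250 Hz).
The two acquisitions are started by hand in separate software, so the
streams are only roughly aligned: the force stream typically leads by
0.5–2.5 s, and neither instrument records the other's clock.  Gait is
periodic but not metronomic — stride times fluctuate by roughly 1–2%
(≈ 8–14 ms at 0.7 s strides) — and that fluctuation is the signal the
synchronization exploits: a window of consecutive stride durations is a
fingerprint that occurs (almost surely) only once in the trial.

## 2. Gait events

*Force stream.*  Foot strike and toe-off are the upward and downward
crossings of a 50 N threshold (`event_config(threshold_n = 50)`).
Crossings are refined to sub-sample precision by linear interpolation
between the two straddling samples (`detect_events_force(subsample = TRUE)`,
the default).  This matters more than it may seem: at 250 Hz,
sample-resolution crossings quantize stride durations by up to ±4 ms —
the same order as the stride-time fluctuation that the synchronization
matches on — and we found that this quantization alone can make a
coincidental window match beat the true one.  The sample-resolution variant
(`subsample = FALSE`) is retained and tested.  Crossings within 50 ms of
the previous accepted crossing are debounced, and events are forced to
alternate starting with a foot strike.

*IMU stream.*  Toe-off is the local minimum of the coronal (mediolateral
axis) angular velocity nearest before each swing peak.  Swing peaks are
local maxima with topographic prominence of at least 30% of the channel's
5th–95th percentile range (amplitude-invariant) and at least 0.4 s apart.
Three robustness measures surround the textbook rule, all configurable in
`event_config()`:

* a 5-sample (20 ms) centered moving average stabilizes extrema
  localization under gyroscope noise; the accepted minimum is then
  re-localized on the raw signal and refined to sub-sample precision by a
  parabolic fit through the three samples around the trough vertex;
* candidate minima must lie in the lower part of the signal range
  (`min_depth_frac = 0.35` of the 5th–95th percentile span above the 5th
  percentile); without this, noise dimples on the flat swing-peak top are
  occasionally the "nearest preceding minimum";
* toe-offs within 40 ms of the recording start are discarded
  (`edge_guard_s`): a trough whose left half is cut off by the window edge
  cannot be localized trustworthily.

A stride is the interval between consecutive toe-offs of the instrumented
(left) leg; durations are reported in ms.

## 3. Sliding time window synchronization

`stws_offset()` takes the two stride-duration sequences.  For window
length *k* (starting at `k0 = 3`):

1. the **standard window** is the *k* durations centred in the IMU
   sequence, `s = floor((N − k)/2)` — the middle of the trial, away from
   edge strides;
2. the RMSE against **every** contiguous window of the force sequence is
   computed (`window_rmse()`);
3. the minimum is adopted only if it is *unique*: the runner-up RMSE must
   exceed `ratio_min × best + tie_tol` (defaults 2.5 and 10⁻³ ms);
4. the argmin is recomputed at *k*+1 and *k*+2; only if all three agree on
   the stride offset is the result confirmed.  Otherwise *k* grows by one
   and the procedure repeats, up to `k_max = min(N, M) − 2` (so the *k*+2
   confirmation window always fits); exhaustion raises a `sync-failure`,
   which is also the defined outcome for degenerate constant-duration
   input.

The relative uniqueness test deserves a note.  An absolute tie tolerance
alone is brittle at this data's scale: both the best and second-best RMSE
are often in the low-millisecond range, and on seeded experiments we
observed (rarely, ≈ 0.1–0.5% of trials) a trial whose duration sequence
nearly repeats over 4–5 strides, so that a wrong window wins *uniquely* at
k = 3–5 and even passes the k+1/k+2 confirmation — only a longer window
separates the repeats.  Requiring the runner-up to be at least 2.5× the
best forces exactly that escalation while leaving clear matches untouched:
across 2,000 simulated trials at study noise levels the offset is recovered
2,000/2,000, with ~90% of trials resolved at k = 3 and a tail reaching
k = 8 — the same qualitative escalation pattern reported for real
treadmill sessions.

The clock correction `time_shift` is computed from the matched pair of
toe-off timestamps (IMU minus force), not from accumulated durations, so it
cannot drift over long trials.  Note the two instruments *define* toe-off
differently (gyro trough vs. 50 N crossing), so `time_shift` carries a
small systematic component (≈ 15 ms here): it is a stride-alignment
correction, not a physical clock difference, and it is applied consistently
on both sides of the stance extraction.

`align_strides()` pairs IMU stride *i* with force stride
*i* + offset over the overlapping range; `stride_time_errors()` reports
MAE/MXAE (ms) and MRE/MXRE (%) of the paired durations, with the force
plate as the reference denominator.

## 4. Stance dataset

Stance is defined purely on the force stream (foot strike → toe-off by the
50 N rule) and transferred to the IMU clock via `time_shift`.  Both
streams are interpolated onto 101 equally spaced points (0, 1, …, 100% of
stance) with natural cubic splines (`stats::spline(method = "natural")`);
natural end conditions avoid endpoint overshoot on the short stance
segments, and splines reproduce linear segments exactly, which the tests
exploit.  vGRF is divided by body weight (mass × 9.81 m/s²); the
acceleration input is deliberately **not** normalized, matching the
modelling premise (and its acknowledged limitation) that the network sees
raw accelerations.

Cycle exclusion (`cycle_rules()`): a cycle is dropped iff its stance
duration falls outside 0.10–0.50 s, its peak vGRF outside 1.0–5.0 BW, or it
contains non-finite values.  The bounds bracket all plausible values for
running at 12–16 km/h; "abnormal" had to be operationalized somehow, and
these rules are deliberately loose so that they fire on corrupt data, not
on ordinary variability.

`build_datasets()` splits by subject (held-out-subject testing; disjointness
is asserted, never assumed) and flattens each sample channel-major:
`x[1..101, axial], x[1..101, sagittal], x[1..101, coronal]` for m = 3, or a
single configured channel for m = 1.  Which anatomical axis "sagittal-axis
acceleration" denotes is genuinely ambiguous (the anteroposterior axis
lies *in* the sagittal plane; the mediolateral axis is *normal* to it); we
default to the anteroposterior channel and expose
`sagittal_channel`/`--sagittal-channel` to change the mapping.

## 5. The WNN and FFNN regressors

Both are single-hidden-layer fully connected networks from the flattened
input (101·m values) to the 101-point stance vGRF curve:

$$z_k = \varphi\!\left(\frac{\sum_{i,j} w_{ijk}\,x_{ij} - b_k}{a_k}\right),
\qquad \hat y_i = \sum_{k=1}^{K} w_{ki}\, z_k - b_i,$$

with φ the Morlet wavelet `exp(-u^2/2) * cos(5u)` (WNN) or the logistic
sigmoid (FFNN).  The ambiguous printed layout of the hidden-layer argument
is read as *division* by the scaling factor a_k — the standard wavelet
network dilation ψ((u − b)/a); a_k is clamped to |a_k| ≥ 10⁻³ after every
optimizer step.  The output bias enters with a minus sign exactly as the
output equation is written; its sign is absorbed during learning.

The loss is the squared error averaged over samples **and** the 101 output
points, plus λ‖w‖² where w spans *all* parameters (hidden and output
weights, shifting factors, scaling factors, output biases); λ = 0.01.
Averaging per point keeps λ's effect comparable between m = 1 and m = 3.
L1 regularization is available (`train_config(reg = "l1")`) but not the
default.

Training (`train_vgrf()`) is plain mini-batch Adam (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁸) with per-epoch reshuffling; defaults are the study's final
hyperparameters: K = 200 hidden nodes, batch 128, learning rate 5·10⁻⁴,
100 epochs.  "Iterations" is interpreted as *epochs* (full passes): with
≈ 350 training samples and batch 128 there are only 3 optimizer steps per
pass, and 100 single steps could not plausibly converge.  Gradients are
analytic (the Morlet derivative −e^{−u²/2}(u cos 5u + 5 sin 5u) is
exercised) and are verified against central finite differences in the test
suite; training is seed-deterministic end to end.

**Initialization.**  Weights are uniform on (−r, r) with r = 1/√(101·m).
The shifting and scaling factors are *not* started at (0, 1): because the
acceleration inputs are unnormalized (magnitudes up to ~70 m/s²), the
hidden pre-activations have per-node means and SDs of order 25, and with
b = 0, a = 1 both activations saturate into numerically dead regions from
which 300 Adam steps cannot recover.  We therefore use the standard
wavelet-network placement: b_k and a_k are set to the mean and SD (floored
at 1) of node k's pre-activations over the training inputs, so every unit
starts in its responsive range; the output bias is set so the initial
prediction equals the mean training curve.  This is a data-dependent but
seed-deterministic initialization, analogous to initializing a final-layer
bias at the base rate.

## 6. Agreement statistics

`curve_metrics()` reports, per curve pair, RMSE (BW, pointwise over the
101 stance points), NRMSE (RMSE over the measured curve's range, in %) and
R² about the measured curve's mean; and across all pairs the coefficient
of multiple correlation in the between-waveform (Kadaba-style) form with
F = 2 waveforms per pair, T = 101 points and G pairs.  The CMC aggregation
rule had to be chosen (grouped over all pairs of a condition); flat curves
make it undefined and yield `NA` with a warning.  `peak_metrics()` uses the
mean measured peak as the NRMSE denominator; with peaks near 2.5–3 BW this
convention makes curve-NRMSE (range-based) and peak-NRMSE (mean-based)
mutually consistent in scale, and makes peak NRMSE ≈ MAPE.
`bland_altman()` uses predicted − measured differences, bias ± 1.96 SD
limits without repeated-measures correction, and warns below 40 pairs,
where limit estimates are unstable.

## 7. The synthetic gait generator

`generate_trial()` emulates one dual-instrument treadmill trial with full
ground truth; `make_cohort()` draws a cohort with between-subject
variation.  What it reproduces:

* **Stance vGRF shapes.**  Raised-cosine (Hann) lobes on the stance-fraction
  axis: forefoot strikers get a single broad lobe (support 0–96% of
  stance, apex at 48%) scaled to `active_peak` (default 2.5 BW); rearfoot
  strikers additionally get a narrow impact lobe (width 20% of stance,
  centred at 14%) whose amplitude is set so the early local maximum equals
  `impact_peak` (default 1.6 BW).  Peaks grow ~2%/(km/h) above 12 km/h and
  vary ~±2% stride to stride.
* **Timing.**  Stride times are i.i.d. Gaussian around the subject mean
  (default 0.70 s at 12 km/h, shortening ~1.8%/(km/h)), truncated at ±3 SD,
  with jitter SD defaulting to 10 ms — the order implied by the stride-time
  agreement the synchronization is expected to deliver, and the property
  STWS fundamentally requires (constant durations are degenerate).
  Contact fraction defaults to 0.32 of the stride.
* **Asynchrony.**  The force clock leads the IMU clock by a uniform draw
  from 0.5–2.5 s, so the force stream contains the lead strides the IMU
  never saw; the true integer stride offset and clock lead are recorded.
  The drawn lead is nudged (≤ 50 ms) so the first counted toe-off sits at
  least 50 ms inside the IMU window — a trough clipped to the first samples
  is not observable, which would make the ground-truth event list
  ill-defined.
* **IMU channels.**  Axial acceleration is gravity + `accel_gain` × vGRF
  (in BW; gain default 25 (m/s²)/BW, giving realistic ~6 g stance peaks)
  plus a decaying 35 Hz sinusoid at each foot strike (stronger for
  rearfoot strikers); the sagittal and coronal channels are scaled copies
  with their own transient weights.  The coronal angular velocity follows a
  fixed per-stride template: maximum at mid-swing, global minimum exactly
  at each toe-off, sharpened by a narrow (60 ms) deep trough — the rapid
  shank reversal seen in running — without which no toe-off detector could
  localize the minimum under gyro noise.
* **Noise.**  Additive Gaussian noise per channel (defaults: 0.5 m/s²
  accelerometer, 5 N force during contact with flight clamped to exactly
  0 N, 0.05 rad/s gyroscope).
* **Ground truth.**  Event times per stream (force events as the analytic
  50 N crossings of the continuous noiseless template, found by root
  solving), the clock lead, the stride offset, realized stride times, and
  each stride's 101-point stance curve in BW.

What it does **not** emulate — and hence what passing tests do and do not
show: there is no musculoskeletal physics; the acceleration-to-vGRF mapping
is a smooth gain plus transient, far more learnable than real soft-tissue
dynamics, so the network accuracies on synthetic cohorts demonstrate that
the pipeline's mechanics (synchronization, segmentation, normalization,
optimization) are correct, not that comparable accuracy transfers to real
runners.  No overground gait, no anteroposterior/mediolateral force
channels, no vendor file formats.

## 8. Problem sizes and determinism

The default cohort mirrors the study design: 8 rearfoot + 7 forefoot
strikers, three speeds (12/14/16 km/h), 16 strides per trial — 720 stance
cycles, of which ~336 train / 48 test per strike pattern after holding out
one subject.  The test suite validates synchronization on hundreds of
seeded trials and trains full-size (K = 200) networks on one cohort; the
acceptance script repeats the recovery experiment on 100 fresh trials and
runs the complete pipeline.  Every random draw — cohort, trials, split,
initialization, batch order — descends from one integer seed, and the
pipeline's serialized report is byte-identical across reruns with the same
configuration.

## 9. Known limitations

* STWS needs stride-time variability; pathologically regular gait (or
  quantization that erases variability) correctly ends in `sync-failure`
  rather than a guess, and trials whose duration pattern nearly repeats can
  require windows up to k ≈ 8 to resolve.
* The stance window is defined only by the force stream; IMU-only stance
  detection (needed for deployment without a treadmill) is out of scope.
* The 101-point grid assumes complete stances; partial edge strides are
  rejected, not imputed.
* Network accuracy numbers obtained on synthetic cohorts characterize the
  implementation, not real-world predictive performance (Section 7).
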