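---
title: "Pre-impact fall detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-impact fall detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preimpact)
```

## The problem

A fall by an older adult lasts well under a second from its onset — the
first deviation from normal movement — to body–ground impact; typical
durations average around 750 ms. A wearable protection system (an
inflatable hip airbag, for instance) must therefore recognise the fall
*during the descent* and still leave a few hundred milliseconds of lead
time for actuation. This package implements pre-impact detection for a
single low-back IMU sampled at 100 Hz with nine channels: three-axis
acceleration (g), three-axis angular velocity (°/s), and three Euler
angles (°) supplied by the sensor's own fusion filter (orientation is
consumed as given; this package does not re-derive it).

Recordings are 11-column CSV files (timestamp, frame counter, the nine
channels); fall trials carry a temporal label with the fall-onset and
fall-impact frame. Between those frames lies the *falling phase*; data
after impact is never used for training or scoring, because a detector
that needs post-impact evidence is useless for prevention.

## Kinematic conventions

The threshold detector consumes four scalar signals per frame:

* `ACC_M`, the L2 norm of the acceleration axes — near 1 g at rest,
  dipping toward 0 during free fall;
* pitch and roll — here the rotations about the sensor X axis
  (sagittal-plane lean) and Z axis (frontal-plane lean), read from the
  stored Euler channels by a configurable name mapping (for this sensor
  placement the y axis is vertical when standing);
* `VV`, the vertical velocity, obtained by rotating the body-frame
  acceleration into the world frame with the per-frame Euler angles,
  taking the vertical component, removing 1 g, and integrating.

Conventions the data do not pin down were fixed once and surfaced as
arguments:

* **Euler composition** is intrinsic Z–Y–X. The vertical projection used
  by `vertical_acceleration()` is insensitive to rotation about the
  vertical axis, so the choice mainly affects how pitch and roll are
  named, not the detector's behaviour.
* **Sign**: downward motion gives positive vertical acceleration and
  velocity, so the 0.3 m/s threshold reads naturally.
* **g = 9.81 m/s² exactly.**
* **Integration drift**: a raw accelerometer integral drifts without
  bound, and whether the original detector high-passed or reset it is not
  recorded. We adopt a stillness-triggered reset — velocity clamps to zero
  after 25 consecutive frames (0.25 s) with vertical acceleration inside
  ±0.2 m/s² — as the minimal mechanism that keeps a 30 s quiet recording
  near zero while leaving the large accelerations of a genuine fall
  untouched. The policy is an explicit argument (`reset_policy`), and
  disabling it recovers the exact trapezoidal integral, which is what the
  closed-form tests check (0.3 s of ideal free fall → 2.943 m/s).

## The detectors

**Threshold rule.** The published operating point — ACC_M ≤ 0.8 g,
VV ≥ 0.3 m/s, |pitch| ≥ 25° or |roll| ≥ 25° — was found by grid search in
the source study. The exact boolean structure of its flowchart is not
recoverable from text alone, so the combination is a configurable
predicate over the four named criteria with the conjunctive form as
default: free-fall dip AND downward velocity AND posture deviation is the
standard multi-criterion pattern in this literature, and a user holding
the original flowchart can reproduce any gating it encodes. Comparisons
are inclusive (≥ / ≤). The detector is causal — the decision at frame *t*
uses no later samples — which the tests verify by truncation. Grid-search
calibration scores every point of the Cartesian grid with the Youden
index computed under the pre-impact rule, breaking ties by longer mean
lead time and then grid order.

**40-feature SVM.** Windows are 50 frames (0.5 s); the stride is not
recorded in the source, so 10 frames is the training default and finer
strides are available for detection timing. For the acceleration and
angular-velocity magnitudes the features are mean, population variance,
RMS, the count of samples above the window mean (called "zero-crossing
rate" in this literature despite the name), the mean absolute deviation
from the window mean, the first five DFT magnitudes, and spectral energy
(Σ|X_k|²/N); for pitch, roll and yaw the variance entry becomes a
standard deviation and the DFT quintet is dropped — 2 × 11 + 3 × 6 = 40
features, in a frozen documented order so saved models are portable.
"First five FFT coefficients" is ambiguous (complex versus magnitude, DC
in or out); we use magnitudes including DC, whose acceleration-magnitude
DC term carries the gravity level that distinguishes free-fall windows.
Features are z-scored with training-set statistics; zero-variance
features are centred but not scaled. The margin classifier itself is
libsvm's RBF machine (`e1071`), C = 1, γ = 1/p, class-balanced weights.

**Conv+LSTM.** Three blocks of [1-D convolution → batch normalisation →
ReLU → max-pool 2] over the raw 9 × 50 window, two stacked LSTM cells
with dropout, and a softmax head; with 50-frame input the temporal axis
contracts 50 → 25 → 12 → 6. Layer sizes (32/64/128 filters, kernel 5,
hidden 128, dropout 0.5, Adam at 1e-3) are defaults, not contracts, and
are configurable; the topology — three blocks, two cells — is fixed. The
network is implemented natively in R with vectorised matrix algebra and
manual backpropagation, which keeps training single-threaded and
bit-reproducible under a seed; the test suite checks the analytic
gradients of every layer against central differences at 1e-4 relative
tolerance. Input channels are standardised with training-set statistics
stored in the model. Channel subsets are supported structurally
(`input_channels`), which is how an acceleration-only variant would be
trained for sensors lacking gyro or orientation data.

**Window labelling** is not stated in the source and is defined here as:
a window is *fall* iff its last frame lies in [onset, impact]; windows
ending before onset are *adl*; windows of fall trials reaching past
impact are discarded. The last frame is the natural timestamp of a causal
streaming decision, and discarding post-impact windows keeps the training
signal strictly pre-impact. For the same reason, the evaluation wrapper
timestamps a positive window at its end frame (configurable to the start
frame).

## Evaluation protocol

Scoring is per file. A fall file is a true positive only if some positive
decision occurs at or before the labelled impact frame — detections after
impact are misses, because the lead time would be negative. Any positive
on an ADL file makes it a false positive. Sensitivity and specificity are
the usual ratios, carried at full precision and rounded to two decimals
only for display; each true positive contributes a lead time
(impact − detection)/rate. Splits are by subject (80/20 by default; 32
subjects split 26/6), never by file, so the test set contains only unseen
people.

## What the simulator is — and is not

The generator emulates the full 36-task taxonomy: 21 ADL types (four
static single-trial tasks, gait at subject-specific frequency and
amplitude with a mid-trial turn, postural transitions with paired
down/up acceleration pulses, a jump with a genuine flight phase, a
stumble transient) and 15 fall types (pre-fall segment of the preceding
activity; a falling segment whose duration is drawn from
Normal(746, 150) ms truncated at 300 ms, with an acceleration-magnitude
dip to 0.15–0.40 g, a monotone downward-velocity ramp and a 60–85°
posture excursion about the fall-plane axis; a 3–6 g impact spike; a
post-fall rest). Signals are generated top-down from an orientation
trajectory and a world-frame acceleration plan, so the accelerometer,
gyroscope and Euler channels are mutually consistent by construction.
Fainting-from-sitting falls rotate fastest at onset while dynamically
preceded falls carry a brief acceleration jerk at onset — the two signal
morphologies the onset-labelling procedure keys on. Channel noise
defaults to 0.01 g / 0.5 °/s / 0.2 °. Every draw descends from one master
seed via per-recording counter-derived sub-seeds, so datasets are
reproducible piecewise.

The simulator is an idealised kinematic sketch, not a biomechanical
model. Its classes are cleanly separable; real falls are not. Passing the
recovery suites therefore demonstrates that the pipeline's contracts,
conventions and plumbing are correct — a detector that missed these falls
would be wrong — but says nothing about field performance on recorded
human data, which is why the published benchmark metrics are reproduced
from their printed confusion counts rather than re-measured.

## Onset labelling

Impact frames are easy (the acceleration spike); onset frames are not.
The assistant selects a *sensitive axis* by fall category — acceleration
y for falls preceded by dynamic movement; for fainting-from-sitting
falls, the gyro axis of the fall plane (x for sagittal, z for frontal
falls) — then ranks local maxima of the absolute signal within a search
window before impact by topographic prominence (ties: earlier frame
first). The window defaults to 1.5 s (mean fall duration plus margin) and
the prominence floor to 0.1 channel units. The final choice among ranked
candidates is deliberately left to a human — the published procedure is
explicitly subjective at this step — with batch mode auto-accepting
rank 1.

## Numerical choices and degenerate inputs

* Population moments (divide by N) everywhere a variance or SD enters a
  feature, for determinism across backends.
* Empty window lists, zero-length feature matrices and empty candidate
  sets return empty containers, not errors; impossible requests (window
  wider than the recording is *not* an error, a label outside its
  recording *is*) follow each operation's documented contract.
* Max-pooling propagates non-finite activations instead of dropping
  them, so divergence in training surfaces as the documented
  "non-finite loss" error with its epoch index.
* Grid-search ties are resolved deterministically (lead time, then grid
  order), and `detect()` breaks simultaneous criterion crossings by
  first frame.

## Problem sizes used by the checks

The bundled verification uses sizes chosen to exercise every code path
at desk scale: a recovery cohort of 6 subjects × 10 tasks × 2 trials
(120 files, ~1,900 windows, capped at 12 ADL windows per file to keep
classes comparable), Conv+LSTM recovery runs with 8/16/32 filters and
hidden size 32 for ≤ 10 epochs on ≤ 2,000 windows, grid search on a
4×4×4×4 grid against an independent brute-force re-scoring, feature
oracles on 1,000 random windows at 1e-9 relative tolerance, and 100
simulated falls for the onset ±50 ms recovery rate. The defaults of
`simulation_spec()` are the study conditions; the cohort sizes above are
the package's own verification choices.

## Known limitations

* The Euler composition order and the label-table column naming are
  conventions adopted here; files from other acquisition stacks may need
  the name-mapping arguments.
* The vertical-velocity reset policy is a design choice absent from the
  source; both behaviours (reset and raw integral) are exposed so they
  can be compared.
* Label tables are read as CSV/TSV; spreadsheet files should be exported
  to CSV first.
* No streaming/embedded implementation and no power or latency
  modelling; the CLI operates on directories of recordings.
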