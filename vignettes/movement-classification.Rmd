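---
title: "Classifying upper-limb movements of stroke patients from wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying upper-limb movements of stroke patients from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Monitoring which movements a hemiparetic stroke patient performs during
daily life — and how much the affected arm participates — is central to
home rehabilitation. Body-worn inertial measurement units (IMUs) make this
feasible, but stroke movement data poses three difficulties that
`strokehar` addresses end to end:

1. **Variability**: the same movement takes very different amounts of time
   across patients, and patients' movement patterns differ from those of
   non-disabled (ND) individuals.
2. **Sparsity**: patient cohorts are small, so a classifier trained on
   patients alone overfits easily.
3. **Asymmetry**: hemiparesis makes unimanual and bimanual-asymmetric
   movements look different on the paretic side, which interacts with
   classification performance.

The instrumentation modeled here is five IMUs — right wrist (sensor 1),
left wrist (2), trunk (3), right upper arm (4), left upper arm (5) — each
reporting accelerometer, gyroscope and magnetometer on x/y/z, i.e. 45 raw
channels at a nominal 80 Hz. Two task families are supported: a
range-of-motion (ROM) task with 14 isolated movements (all unimanual) and
an activities-of-daily-living (ADL) task with 56 movements spanning
unimanual (UNI), bimanual-asymmetric (BIA) and bimanual-symmetric (BIS)
types. A *segment* is one annotated movement instance.

## Pipeline

### Loading and exclusion

`read_recording()` / `load_dataset()` read a CSV dialect (timestamp + 45
channels, plus an annotation table with half-open 0-based `[start, end)`
indices). Rows with unparseable cells are dropped and counted. A
participant whose task data miss **more than one** movement segment is
excluded entirely; exactly one missing segment is tolerated. Annotations
that fall outside their recording are rejected and count as missing.

### Preprocessing (`preprocess_dataset()`)

Per segment, in this order:

1. **Zero-centering** — every channel's segment mean is subtracted.
2. **Channel selection** — magnetometers are dropped (they depend on
   heading relative to the Earth's field), leaving 30 channels
   (5 sensors × acc/gyro × x/y/z). Single-sensor ablations
   (6-channel "S1-all", 3-channel "S1-acc") are expressed through
   `channel_subset()`.
3. **Side swapping** — for left-hemiparesis participants the left/right
   wrist and upper-arm channel blocks are exchanged, so the affected-limb
   activity occupies the same channels for everyone.
4. **Linear interpolation** to a fixed length *T* (ROM 1000, ADL 3700
   points). The abscissa is the sample index, not the timestamp; the
   operation is exact on signals affine in the index. We center before
   interpolating and do not re-center afterwards (the interpolated signal
   is no longer exactly zero-mean; the difference is a second-order
   effect).
5. **Sliding windows** — window/stride 200/42 (ROM) or 740/150 (ADL),
   giving `floor((T - w)/s) + 1 = 20` windows per segment for both tasks.
   Trailing samples not covered by the last window are discarded. The
   fixed window count is the point: every (participant, class) pair
   contributes equally, removing class imbalance caused by variable
   durations.

### Asymmetry score (`segment_asymmetry()`)

For zero-centered values \(x_{c,t}\), side energies are

\[
E_R = \frac{1}{N_R}\sum_{c \in RC}\frac{1}{T}\sum_{t=1}^{T} x_{c,t}^2,
\qquad
E_L = \frac{1}{N_L}\sum_{c \in LC}\frac{1}{T}\sum_{t=1}^{T} x_{c,t}^2,
\]

with \(RC\)/\(LC\) the 12 acc+gyro channels of the right (sensors 1, 4)
and left (2, 5) sides, and

\[
S_\mathrm{asym} = \log\frac{E_R + \epsilon}{E_L + \epsilon},
\qquad \epsilon = 0.001 .
\]

\(S_\mathrm{asym}\) is positive for right-dominant energy, negative for
left-dominant, zero at equality; its absolute value (AAS) measures
one-sidedness regardless of side. Scores are computed on *unswapped*
segments (the sign carries the side information that swapping would
erase) and, by default, on segments interpolated to a common length so
that \(T\) is constant across compared segments; a raw-length mode is
available via `interpolate_to = NULL`. `aas_by_movement_type()`
aggregates \(|S_\mathrm{asym}|\) per movement across participants first,
then across the movements of each type; a pooled mode exists as an
option.

### Axis-rotation augmentation (`augment_dataset()`)

A training set is doubled by adding one rotated copy of each segment:
a random angle uniform on \((-90^\circ, +90^\circ)\) about a random axis
uniform on the sphere (Rodrigues construction), applied to every
(sensor, modality) x/y/z triplet. Design choices, made where the
operation admits variants:

* one rotation is shared by all triplets of a segment
  (`scope = "per_segment_global"`), emulating a whole-body orientation
  change; a per-sensor mode exists;
* rotation is applied at the segment level *before* windowing, so all
  windows of a segment share one rotation;
* gyroscope triplets rotate exactly like accelerometer triplets (angular
  rate transforms as a vector under frame rotation).

Rotation is an isometry on each triplet, so side energies and
\(S_\mathrm{asym}\) are invariant under it — a property the tests
exploit across modules. Augmentation is applied to training folds only,
never to evaluation data.

### The classifier (`har_cnn()`)

A 1-D convolutional network applied to `[time × channel]` windows:

* four convolutional layers, kernel 5, stride 2, valid (no) padding,
  with 32/64/128/256 features — feature lengths 200→98→47→22→9 (ROM)
  and 740→368→182→89→43 (ADL);
* flatten (9×256 = 2304 resp. 43×256 = 11008), then dense layers of 800
  and 200 units with dropout p = 0.7 (training only), then a dense output
  layer of `n_classes` units and a softmax;
* ReLU on every layer. The architecture description applies ReLU to the
  output layer *before* the softmax as well; `model_config(final_relu=)`
  controls this. The literal form is the default for fidelity, but note
  it is numerically fragile: once every output logit of a batch is
  rectified to zero the softmax is uniform and the gradient vanishes
  identically, so the output layer can die irrecoverably. At the small
  problem sizes used for testing this happens within one epoch, so all
  *training-based* examples and checks in this package use
  `final_relu = FALSE` (the conventional softmax head); at the original
  study's data scale the literal head can escape the dead regime, and
  both modes are exported.

Training is minibatch AdamW (decoupled weight decay applied to all
parameters) with learning rate 0.001, betas (0.9, 0.999), eps 1e-8,
weight decay 0.01, cross-entropy loss, batch 256 windows, 40 epochs,
no schedule, no early stopping; final-epoch weights are kept. The whole
forward/backward pass (im2col convolutions, dense layers, dropout,
softmax/cross-entropy) and the optimizer are implemented in base R
matrix algebra and verified against numerical differentiation in the
test suite. He-normal initialization with zero biases; all randomness
(initialization, shuffling, dropout) derives from one seed, so fits are
bit-reproducible on a given BLAS. Inference disables dropout;
probability rows sum to 1 and argmax ties break toward the lowest class
index.

### Evaluation (`run_condition()`)

Three training conditions, evaluated on the Stroke group:

* **ND** — train once on all ND participants, evaluate every Stroke
  participant (plain split);
* **Stroke** — leave-one-subject-out (LOSO) over Stroke participants;
* **ND+Stroke** — LOSO over Stroke participants with all ND data always
  in the pool.

Setting `evaluation_group = "ND"` runs LOSO over ND participants
instead. Per held-out participant, one-vs-rest precision/recall over the
participant's windows gives one F1 per (participant, class); F1 = 0 when
precision + recall = 0. A segment-level mode (majority vote over a
segment's windows first) is provided because the evaluation unit is
ambiguous in principle; window-level is the default. Reports carry
per-participant means, group mean ± SD with min/max participants,
movement-type summaries (`movement_type_summary()`), row-normalized
confusion matrices from pooled held-out predictions and ranked confused
pairs. Fold seeds are derived deterministically from the training seed,
and the held-out participant is asserted absent from every training
pool. When augmentation is enabled, one rotated copy of every segment is
drawn once per run and folds use the copies of their own training
participants — equivalent in distribution to redrawing per fold, at a
quarter of the cost. The per-condition statistics are descriptive
(mean ± SD and matched-seed directional comparisons); inferential
modeling across conditions is out of scope.

## The synthetic generator

`generate_dataset()` produces datasets with the structure above so every
stage is testable without recordings:

* Each movement class has a deterministic template per channel: a sum of
  2–4 sinusoids whose frequencies (0.3–3 Hz by default, a realistic band
  for upper-limb movement at 80 Hz) and phases are fixed low-discrepancy
  functions of (movement, channel, harmonic). Distinct classes are
  pairwise distinguishable (flattened-template correlations < 0.95),
  which makes recovery experiments well-posed.
* Segment lengths are drawn from a truncated normal floored at 240
  points, ROM mean 1016 / SD 492, ADL 4229 / 3072. The underlying
  location is solved (by `uniroot` on the closed-form truncated-normal
  mean) so that the *post-truncation* mean equals the requested mean;
  naive truncation of the nominal distribution would inflate the ROM
  mean by about 6%.
* Movement-type asymmetry: the active side (right for ND and
  right-hemiparesis, left for left-hemiparesis participants — patients
  perform one-sided movements with the affected limb) keeps amplitude 1;
  for UNI and BIA the other side is scaled so the template energy ratio
  equals `asym_energy_ratio` (defaults UNI 110, BIA 1.65, BIS 1,
  i.e. log-ratios ≈ 4.7, 0.5, 0, mirroring the reported ordering
  UNI ≫ BIA > BIS).
* Stroke realism: log-normal amplitude jitter (SD 0.3) and phase jitter
  (SD 0.4 rad) on the affected side's channels per segment, and a 1.25×
  duration inflation. These magnitudes are chosen once as "moderate"
  distortion; they are not calibrated to any real recordings.
* Participant variability: a log-normal amplitude scale (SD 0.1) and a
  phase offset (SD 0.2 rad) per participant. Additive white noise
  (SD 0.05) on all channels. Magnetometer channels carry a large slowly
  varying offset plus noise, mimicking heading dependence; they are
  excluded downstream.

What the generator does **not** emulate: biomechanically realistic limb
kinematics, within-segment repetition structure (real segments contain
five repetitions), sensor artifacts (drift, clipping, dropped packets)
and realistic between-class similarity structure. Passing recovery tests
therefore demonstrates that the pipeline is correct and that the model
can learn participant-invariant classes under distortion and orientation
nuisance — not that any particular F1 level transfers to real recordings.

## Problem sizes used by tests and the acceptance script

Desk-scale experiments use reduced dimensions chosen as the package's
own test design: the parameter-recovery experiment uses 12 participants
(8 ND, 4 Stroke), 8 classes, mean length 400 ± 100, windows of 160
points with stride 5 (49 windows/segment), and pooled ND+Stroke LOSO at
10 epochs; the trend experiments (joint vs Stroke-only training,
augmented vs original under test-time rotation nuisance, BIS vs BIA
difficulty for the Stroke-like group) use 9 participants, 6 classes,
64-point windows and 8 epochs, averaged over three seeds. The test-time
orientation nuisance there uses a ±45° angle range — a moderate
orientation shift that degrades but does not destroy an unaugmented
model, so the between-condition comparisons remain informative — while
the augmentation itself keeps its ±90° range. Full-scale
ROM/ADL presets are exported and used for the architecture and windowing
arithmetic.

## Numerical choices and edge cases

* Interpolation requires ≥ 2 samples; endpoints are reproduced exactly.
* `asymmetry_score` rejects negative energies; a single-member
  aggregation group reports SD 0.
* Cross-entropy clamps probabilities at 1e-12 before the log.
* Dropout uses inverted scaling, so inference needs no rescaling.
* `windows_per_segment` is validated against the preset contract
  (20 windows for both tasks) in the tests rather than enforced for
  custom configurations, where any count ≥ 1 is legal.

## Known limitations

* The literal ReLU-softmax head (see above) is exported but fragile at
  small scale.
* Real-data annotation schemas vary; the column-map mechanism in
  `read_annotations()` exists because the released dataset's exact
  layout is not fixed by the package.
* Training is pure R; it is practical at the tested scales (minutes per
  LOSO experiment) but not at the original study's scale (thousands of
  long windows × 40 epochs), where a GPU framework would be the right
  tool.
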