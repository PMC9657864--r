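---
title: "Fall prediction from skeleton key-point kinematics: models and methods"
author: "fallsafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall prediction from skeleton key-point kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsafe)
```

## The problem and the data model

Falls are a leading cause of injury in older adults, and video is an
attractive sensing modality because it requires nothing attached to the
person. `fallsafe` classifies short stretches of skeleton key-point
motion — the nose (N), left shoulder (LSh) and left hip (LH), as a pose
estimator tracks them frame by frame — as *fall* or *not-fall* (an
activity of daily living, ADL).

Coordinates live in the image frame: the origin is the outer left
corner, x grows to the right, **y grows downward towards the floor**,
and z points out of the frame. The z coordinate is carried through the
data contract but used by no feature: the kinematic quantities below
depend only on x and y. Streams arrive at a nominal ~18 Hz; real
timestamps are authoritative for time steps, which in practice jitter
around 1/18 s.

## Per-frame kinematic features

For each tracked key point $i \in \{N, LSh, LH\}$ at image coordinates
$(X_i, Y_i)$, three quantities are computed per frame:

1. **Angle to the origin.** $A_i = \arctan(Y_i / X_i)$, the angle
   between the line joining the key point to the image origin and the
   x-axis, in radians. The formula is implemented exactly as printed,
   with a guard: when $|X_i|$ falls below a small epsilon the limit
   value $\mathrm{sign}(Y_i)\,\pi/2$ is returned with a warning. In the
   stated image frame coordinates are positive, so the guard is a
   numerical safety net rather than an expected path.
2. **Angular rate.** $dw_i[k] = (A_i[k] - A_i[k-1]) / (t[k] - t[k-1])$
   in rad/s, from real timestamps. The first frame of a trial has no
   predecessor; its rate is 0 by convention, which keeps one feature row
   per frame and affects at most the first window of a trial.
3. **Nose-to-hip height ratio.** $R = N_y / LH_y$. Because y points
   down, $R < 1$ while the nose is above the hip and $R > 1$ once the
   head is at or below hip height — the closer the head to the floor,
   the larger $R$. A frame with $LH_y = 0$ has no defined ratio and is
   treated as unreadable.

Three classifier variants differ only in which columns they consume:

| variant | features | m |
|---|---|---|
| 4p | $N_x, N_y, dw_N, R$ | 4 |
| 5p | $N_x, N_y, dw_N, dw_{LSh}, dw_{LH}$ | 5 |
| 6p | $N_x, N_y, dw_N, dw_{LSh}, dw_{LH}, R$ | 6 |

The kinematic rationale: a fall shows a large $dw_N$ *and* $R$ rising
through 1 (head approaching the floor); an intentional bend shows a
moderate $dw_N$ with quiet shoulder/hip rates and $R$ staying below 1;
a stumble that the person recovers from shows intermediate rates but
never drives $R$ through 1. The richer sets resolve precisely the cases
the four-parameter set confuses.

## Preprocessing, windowing and splits

Frames whose key points could not be read are dropped individually.
Frames at or after the first post-impact frame of a trial (the person
has hit the floor; represented as a per-frame boolean supplied by the
data producer, since "hands touched the floor" is a visual judgement
with no computable definition) are dropped as a block — nothing after
impact carries pre-fall information. The on-disk dialect therefore
carries two flags, `excluded` and `post_impact`; the latter is optional
on read.

Class balance is restored by **down-sampling only**: whole contiguous
blocks are removed from the tails of randomly chosen (seeded)
majority-class trials until the two classes agree to within one window
length. Rows are never synthesised, and surviving stretches remain
valid time series — row-wise random deletion would destroy the temporal
structure an LSTM consumes.

The feature stream is then cut, per trial, into **non-overlapping
18-frame windows** (about 1 s at 18 Hz); a trailing remainder shorter
than a window is dropped. A window is labelled *fall* if **any** of its
frames is a fall frame: the system's purpose is alarming, so the rule
favours recall. A majority-vote rule is available
(`makeWindows(..., labelRule = "majority")`).

Splitting preserves temporal order (no shuffling): the first
`round(0.69 n)` windows form the train+validation block, of which the
last 20% are validation; the rest is the test set. Fractional sizes
round half up. The published accounting of its source data is
internally inconsistent (5220 training rows imply 290 windows, yet 327
training packs are reported); the package therefore exposes the split
as *fractions*, and the worked 327/96 example is reproduced by passing
`trainFraction = 327/423` explicitly. Whether the original split was by
subject, trial or time is unstated; the package splits the concatenated
temporal stream, the simplest reading consistent with "not shuffled".

## The classifier

All variants share one architecture, built by `buildModel()`:

```
input (18 x m) -> LSTM(100, return sequences) -> LSTM(100)
              -> dropout(0.3) -> dense(1, sigmoid)
```

with Adam (learning rate 0.001), natural-log binary cross-entropy
loss, 50 epochs and batch size 64 as defaults — the published network
setting. Two sources of ambiguity in that setting are resolved as
follows, both configurable: the architecture narrative describes two
stacked LSTM layers (the summary table says one hidden layer; the more
detailed source wins), and the relu activation is applied where an
inner activation choice exists — the LSTM cell/candidate
activations — while gates and the output neuron are sigmoid. Dropout is
a single layer after the second LSTM, not per-layer recurrent dropout.
A window is called a fall when its sigmoid score reaches the decision
threshold, 0.5 by default (the `>=` convention; the threshold is never
stated in the source setting and is exposed in `ModelConfig`).

The LSTM engine is implemented in the package as batched base-R matrix
code (forward pass, backpropagation through time, Adam): every
time-step update is a handful of BLAS matrix products over the whole
batch. Correctness is pinned by two independent oracles in the test
suite: finite-difference gradient checks on a tiny network, and a
closed-form trainable-parameter count,
$4H(H{+}m{+}1) + 4H(2H{+}1) + (H{+}1)$ for two layers of $H$ units.

### Numerical choices

* **Initialisation**: Glorot-uniform input kernels, orthogonal
  recurrent kernels (one orthogonal block per gate), forget-gate bias
  1 — the standard LSTM recipe; all seeded and bit-reproducible.
* **Gradient clipping** (`clipNorm = 1`, configurable): relu cell
  activations are unbounded, and on small datasets late-training
  gradient spikes can undo a converged fit; clipping the global
  gradient norm is the standard remedy. `Inf` disables it.
* **Best-epoch restoration** (`restoreBest = TRUE`): the final model is
  the one from the epoch with the lowest validation loss. This is the
  validation split's standard model-selection role; the full per-epoch
  history is always retained. Set `FALSE` to keep last-epoch weights.
* **Score clipping**: reported cross entropy clips scores at `1e-12`
  from the boundary (with a warning) so confident saturated predictions
  stay finite.
* **Training length**: epochs default to the published 50. When a
  dataset is much smaller than the original (fewer windows means fewer
  batches per epoch), the comparable condition is the published
  *optimization budget* in Adam steps — roughly 300, i.e. 50 epochs
  times six 64-window batches — rather than the epoch count; pass
  `epochs` to `trainModel()`/`runEndToEnd()` to match it. The default
  synthetic study converges within the default 50 epochs.

## Evaluation

Falls are the positive class. Precision, recall, their harmonic mean
F1, and accuracy are reported on the 0–100% scale from the confusion
counts. The printed per-class-averaged forms reduce to the standard
single-positive-class formulas for a binary task, which is what
reproduces the published precision/recall/F1 relationships; a
macro-average is available. A metric whose denominator is zero is
reported as *undefined* (`NA`), never as 0, and flagged in the report.
The reporting loss is the base-2 cross entropy **summed** over windows
(the worked example — truth 1, score 0.5, loss 1 bit — pins both the
base and the sum), while the training objective is the natural-log
mean binary cross entropy.

## The synthetic motion simulator

The original study used recorded videos of 17 subjects; those are not
shipped. `simulateDataset()` instead generates labelled key-point
streams from a two-rod chain — hip to shoulder (trunk, 0.28 image
units) and shoulder to nose (neck, 0.14) — whose trunk angle follows a
smooth, analytically checkable raised-cosine profile per scenario, plus
seeded Gaussian jitter on every coordinate (sd 0.004 image units,
about 2.5 px at 640 px width, emulating pose-estimation error) and 2%
jitter on frame intervals. Seven scenarios cover the kinematic
contrasts that matter:

* **stand, walk, sit**: trunk near vertical, rates bounded by
  `adlMaxAngularRate` (1 rad/s), $R$ well below 1;
* **bend_intentional**: trunk pitches to ~1 rad and returns, nose rate
  moderate, shoulder/hip rates small, $R < 1$ throughout;
* **fall_forward, fall_sideward**: trunk rotates from vertical past
  horizontal with peak rate `fallPeakAngularRate` (3.5 rad/s — the
  separability knob, strictly above the ADL bound), the hip drops, and
  $R$ crosses 1 before the simulated impact; frames from impact on are
  flagged post-impact. The pre-fall lead-in is short (0.2 s) so a
  retained fall trial is about one window containing both the
  high-rate ramp and the $R > 1$ crossing;
* **near_fall_recovered**: the trunk pitches to ~1.2 rad (short of
  horizontal) at an intermediate rate — between the ADL bound and the
  fall peak — then recovers; $R$ never reaches 1. Labelled not-fall
  (synthetic activity code 12, an extension of the 11-activity
  convention in the default activity map).

Defaults (18 Hz, 40 trials per scenario across all seven scenarios)
define the package's standard synthetic study: 280 trials,
roughly 16k frames, and — after balancing and windowing — about 150
windows. Trials are interleaved round-robin across scenarios so the
unshuffled temporal split sees both classes on each side, as when
subjects perform each activity in turn.

What the simulator deliberately does **not** model: biomechanics
(masses, forces, energies), pose-estimator failure modes with temporal
correlation (occlusion, identity switches), multi-person scenes, camera
view changes, and the full 5-fall/6-ADL taxonomy. Noise is independent
per frame. Passing the pipeline's tests on this data therefore shows
that the implementation is correct and that the *designed* kinematic
contrasts are learnable; it does not certify accuracy on real video.

## Design decisions that were genuinely open

* **Window label rule**: "any fall frame" (recall-favouring) over
  majority vote; both implemented.
* **Balancing granularity**: trial-tail blocks rather than random rows,
  to keep time series valid for the LSTM.
* **Split rounding**: round-half-up, documented, since only "around
  69%/31%" is specified.
* **First-frame angular rate**: 0 by convention.
* **Batch order**: temporal, never reshuffled between epochs, matching
  the "not shuffled" statement; a `shuffle` flag exists.
* **Unreadable-frame detection**: deferred to the data producer as a
  boolean flag; the original criterion (confidence threshold vs.
  absence) is unstated.

## Known limitations

* The 4p variant is genuinely the weakest, as in the original ranking:
  at reduced optimization budgets its errors concentrate on recovered
  near-falls whose first second resembles fall onset through nose
  coordinates alone.
* Real pose-estimation error is temporally correlated and
  heavy-tailed; the Gaussian jitter here is a documented
  simplification.
* Percentages and counts printed by the original study at its own data
  scale (e.g. headline accuracies of 96.99/97.74/98.5%) are not
  reproducible without the original videos; the synthetic study
  reproduces the *relationships* (ordering of variants, worked F1 and
  windowing arithmetic) and the attainable-accuracy regime.

## Problem sizes used by the shipped experiments

The test suite runs unit oracles on toy networks (≤ 8 units, ≤ 6
frames) in milliseconds; the end-to-end acceptance experiment uses the
default synthetic study (40 trials × 7 scenarios), five seeds × three
variants at the default 50 epochs, a few minutes in total on one CPU.
The acceptance script repeats that experiment and the windowing/F1
worked examples from scratch at the same sizes.
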