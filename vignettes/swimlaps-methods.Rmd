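---
title: "Swimming activity recognition and lap timing from a single sacral IMU: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swimming activity recognition and lap timing from a single sacral IMU: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single waterproof inertial measurement unit (IMU) fixed on the sacrum —
three accelerometer axes in g, three gyroscope axes in deg/s, sampled at
280 Hz — records everything a swimmer does in the pool. Turning that raw
signal into training metrics requires two things: a per-frame classification
of the activity (which stroke is being swum, and the transition phases
around it), and lap times derived from the transitions between those
activities. `swimlaps` implements this pipeline end to end:

1. **preprocess** — low-pass filter, downsample to a 50 Hz working rate,
   standardize each channel;
2. **window** — cut the six-channel series into 1.8 s sliding windows;
3. **classify** — a stacked bidirectional LSTM assigns each window's median
   frame one of eight classes: wallpush (WP), underwater (UN), butterfly
   (BU), backstroke (BA), breaststroke (BR), front crawl (FR), turn (TU),
   rest (RS);
4. **filter** — remove implausibly short predicted segments;
5. **lap times** — anchor lap boundaries on class transitions and emit typed
   laps (START / MIDDLE / END);
6. **agreement** — score lap times against a reference with bias, typical
   error of measurement (TEM), Bland–Altman limits and MAPE.

Because no public corpus of labelled sacral-IMU swimming data exists, the
package also ships a synthetic session simulator so that every stage is
testable from code alone.

## Preprocessing

Raw 280 Hz signals pass through a second-order Butterworth low-pass at
10 Hz, applied forward and backward. The zero-phase choice matters: a causal
filter would delay every channel by a rate-dependent group delay and shift
every detected lap boundary with it. The cost is that the effective
magnitude response is the squared one-pass response, so the nominal cutoff
sits at the half-power point of the two-pass filter; the test suite pins
this down (amplitude ratio 0.50 for a 10 Hz sinusoid). End transients are
suppressed by odd-reflection padding (eight filter time constants), so a
constant signal passes through unchanged.

Downsampling to 50 Hz is a non-integer factor (5.6), handled by natural
cubic-spline interpolation onto the uniform 50 Hz grid. With the signal
already band-limited to 10 Hz — a fifth of the new Nyquist — interpolation
error is negligible (the suite requires < 1e-3 against an analytic
sinusoid).

Standardization subtracts the per-channel mean and divides by the
per-channel standard deviation, `(x - mean) / sd`, with the sample (n−1)
convention fixed for reproducibility. The scaler is fitted **on training
subjects only** and applied unchanged to validation and test subjects.
Pooling the held-out subjects into the scaler would leak information across
the subject-wise split; fitting on everything remains possible by passing a
scaler fitted on all recordings, but the train-only scope is the default
the experiment helpers use.

Order is fixed as filter → downsample → standardize; standardizing before
downsampling would give the same result up to interpolation linearity, but
one order had to be fixed and this one keeps the scaler defined on the
working rate the classifier sees.

## Windowing and tensor layout

Windows are 90 frames (1.8 s at 50 Hz), long enough to contain at least one
full cycle of every phase, sliding with stride 1 so a prediction exists for
every 0.02 s frame. Each window is labelled with the class of its median
frame, 0-based index 45 of 0..89. Edge frames are covered by replicating
the boundary frame so the first and last 45 frames also receive
predictions.

The input tensor layout deserves a note. For `n` windows of 6 channels and
90 frames, the network consumes, per window, a **sequence of 6 steps whose
features are that channel's 90-frame vector** — not the conventional 90
steps of 6-channel frames. This is the layout under which the per-layer
parameter counts of the reference architecture work out exactly (first
bidirectional layer: 2·4·64·(90+64+1) = 79,360, and so on down the stack),
and `model_config(strict_reference = TRUE)` enforces those counts at
construction. The conventional layout is available as
`layout = "frames_as_time"`, but it produces a different (smaller) network
and is refused under `strict_reference`.

## The classifier

The network is four stacked bidirectional LSTM layers of 64/32/16/16 units
per direction (tanh activations; dropout 0.25 and recurrent dropout 0.25),
the last one returning only its final states, followed by a dense ReLU
layer of 50 units, batch normalization, dropout 0.5, and a dense softmax
over the 8 classes. Per-layer parameter counts are
79,360 / 41,216 / 10,368 / 6,272 / 0 / 1,650 / 200 / 408 (the batch-norm
200 counts its moving statistics, as deep-learning framework summaries
conventionally do).

There is no deep-learning framework dependency: forward pass,
backpropagation through time, ADAM, dropout and batch normalization are
implemented in compiled code (RcppArmadillo). This keeps the package
self-contained and the training loop deterministic for a fixed seed in
single-threaded execution. The sequence length of 6 in the default layout
makes BPTT cheap. Gradient correctness is not taken on faith: the test
suite checks analytic gradients for every parameter family against central
finite differences on a small network (agreement to ~1e-9 relative).

Training uses sparse categorical cross-entropy, Xavier-uniform weight
initialization (forget-gate biases at 1, the usual LSTM stabilization),
minibatches of 64, and 10 epochs with an initial learning rate of 0.001.
The learning-rate decline is implemented as the closed form

&nbsp;&nbsp;&nbsp;&nbsp;`lr(e) = 0.001 · 800^(−e/100)`,

a geometric decay of ~6.5% per epoch: the schedule is a pluggable function
(`lr_schedule()`) and its parameters (`lr_base`, `lr_scale`) are
configuration, so other declines can be swapped in. Class-weighted loss is
available (`class_weights` in `training_config()`) but off by default: on
the synthetic cohorts the unweighted loss is sufficient, and weighting
interacts with the filtering stage in ways that are better studied
explicitly than silently defaulted.

Batch normalization uses batch statistics during training with moving
averages (momentum 0.99) frozen at inference — standard semantics.
Numerical constants: batch-norm epsilon 1e-3 and ADAM epsilon 1e-7, the
common framework defaults.

### Subject-wise splitting

`split_hoscv()` holds out whole subjects: one for validation (epoch-wise
monitoring) and one for testing. Using the *same* subject for both would
let validation-guided choices leak into the test estimate, so the default
draws two distinct subjects; `single_holdout_subject = TRUE` reproduces the
single-subject variant for comparison.

### Training stride

Prediction is always stride 1 (one label per 0.02 s frame). For *training*,
the stride between window starts is configurable: consecutive windows
overlap in 89 of 90 frames and are nearly redundant as training samples.
The experiment helper defaults to stride 6 (0.12 s between training
windows), which keeps a six-subject experiment tractable on a single CPU
core without changing the per-frame prediction semantics. Stride 1
reproduces the fully dense training set.

## Prediction filtering

Raw per-frame predictions contain isolated misclassified frames and brief
"skips" at phase boundaries. The filter enforces a per-class minimum
segment duration: while any interior segment is shorter than its class
minimum, the shortest violating segment is reassigned to its longer
neighbour (ties favour the preceding segment) and equal-class runs are
re-merged, to a fixpoint. The rule is deliberately the simplest one
consistent with "remove artefacts and prediction skips"; the policy object
(`filter_policy()`) carries the per-class minima so alternative rules or
durations can be configured. Defaults (WP 0.2 s, UN 0.5 s, TU 0.6 s,
RS 1.0 s, strokes 1.5 s) reflect phase physiology and are package choices,
not published constants. The first and last segments of a recording are
exempt — a session may legitimately begin or end mid-phase. Each iteration
removes one violating segment, so termination is guaranteed; an iteration
cap raises a warning as a belt-and-braces guard.

The filter never changes the frame count or timebase, is idempotent, and
on the synthetic benchmarks strictly increases weighted F1 when applied to
predictions with a small fraction of corrupted frames (this is asserted in
the acceptance suite rather than claimed here).

## Lap times

A *swim block* is a maximal run of non-rest segments. Lap anchors within a
block depend on the technique:

* **Front crawl and backstroke** (tumble turns): the anchor is the end of a
  wallpush segment when one exists, otherwise the first frame of an
  underwater segment not immediately preceded by a wallpush (the post-turn
  glide). The fallback matters because predicted sequences often miss the
  very short wallpush entirely.
* **Butterfly and breaststroke** (hand-touch turns): the first anchor is
  the end of the initial wallpush; every turn start (the wall touch) is an
  intermediate anchor.
* The final anchor of every block is the first frame of the rest segment
  terminating it.

One lap per inter-anchor interval; the first lap of a multi-lap block is
typed START, the lap ending at rest END, the others MIDDLE. A single-lap
block is typed END — it terminates at rest, which is END's defining
property. Each lap's technique is the *dominant* stroke class inside its
interval, which tolerates brief misclassified stroke frames. For middle
laps of tumble-turn techniques the anchor could arguably be the turn start
rather than the post-turn glide; the anchor abstraction
(`detect_boundaries()`) isolates this choice, and the wallpush/underwater
convention was kept because it matches the wallpush-to-wallpush definition
used for the hand-timed reference.

Applied to ground-truth labels, these rules reproduce the simulator's lap
table exactly (within one frame), which the test suite uses as an oracle on
dozens of random sessions.

## Agreement statistics

For paired lap durations (predicted vs reference):

* **bias** — mean difference, CI from the t distribution with n−1 df;
* **TEM** — sd(differences)/√2, the within-pair standard error of a single
  measurement; CI from the chi-squared distribution of (n−1)s²/σ². The /√2
  convention is stated explicitly because "typical error" has variants;
* **Bland–Altman** — limits of agreement at bias ± 1.96 sd, no
  regression-based proportional-bias variant;
* **MAPE** — mean(|pred−ref|/ref)·100, its SD being the SD of per-pair
  absolute percentage errors, and a seconds form MAPE/100 · mean(ref).

F1 is the standard harmonic mean 2PR/(P+R); macro and support-weighted
averages are both reported, with the confusion matrix oriented rows =
truth. The CI conventions (t, chi-squared) are package choices where the
field's reporting habits are silent; coverage of the TEM interval is
checked empirically in the acceptance suite (nominal 95%, accepted within
92–98% over 200 simulations).

## The simulator

`generate_session()` assembles sessions from a block grammar — wallpush →
underwater glide → stroke, laps separated by turn → underwater, each block
closed by rest — mirroring a progressive training protocol in which each
block sweeps four pace levels (low / moderate / high / maximal, lap-time
targets of roughly 30/26/23/20 s on a 25 m basis). Signal primitives per
phase:

* WP: half-sine acceleration impulse on the cranial axis (~1.5 g);
* UN: decaying ~2.2 Hz undulation on the z accelerometer and pitch
  gyroscope;
* strokes: one or two harmonics at technique-specific base frequencies
  (BU 0.90, BA 0.70, BR 0.55, FR 0.75 Hz) with technique-specific channel
  weighting — roll-dominant gyroscope for BA/FR, surge spikes on the
  cranial accelerometer for BR, undulation for BU — plus a gravity
  orientation cue on the z accelerometer separating supine backstroke from
  the prone techniques;
* TU: a high-amplitude half-period gyroscope burst (roll axis for tumble
  turns, yaw for open turns);
* RS: near-zero dynamics with gravity on the cranial axis (upright at the
  wall).

All phases carry additive Gaussian sensor noise (0.05 g accelerometer,
4 deg/s gyroscope). Inter-subject variability enters through per-subject
multiplicative amplitude, stroke-frequency and lap-duration scales and
jittered pace multipliers; intra-subject variability through the pace sweep
within each block. Pace scales stroke frequency (∝ √speed), amplitude
(∝ speed) and lap duration (∝ 1/speed). All randomness flows from explicit
seeds; fixed inputs reproduce a session bit for bit.

The stroke frequencies and amplitudes are *plausible placeholders*, not
fitted values — no per-phase amplitudes or stroke frequencies are published
for this setting — and every one of them is config-overridable. What the
simulator deliberately does **not** model: soft-tissue artefact, gyroscope
temperature drift (an AR(1)/drift hook exists but is off by default),
hydrodynamic signal coupling, diving starts, leg-kick-only phases, or
inter-lane interference. Consequently, passing tests on synthetic cohorts
demonstrate that the pipeline is implemented correctly and that the
classifier can exploit class-separable structure under subject-wise
generalization — they do not certify field performance on real swimmers,
whose signals are harder in exactly the ways the simulator idealizes.

## Problem sizes in the test and acceptance suites

The acceptance experiment uses a 6-subject cohort (four 4-lap blocks per
session, one per technique, ~10 minutes of signal each), 10 training epochs
at training stride 6, averaged over 3 seeds; it requires mean weighted F1
≥ 0.90 on the held-out subject after filtering and lap-time MAPE ≤ 2%
against the simulator's ground truth. These sizes are the package's chosen
desk-scale study conditions: large enough for subject-wise generalization
to be non-trivial, small enough to run routinely. The lap-time oracle is
checked on 50 random sessions per run, and the statistical estimators
against brute-force recomputation and Monte-Carlo simulation.

## Known limitations

* The filtering rule is a declared reinterpretation of an unpublished
  artefact-removal procedure; other rules fit behind the same policy
  object.
* The learning-rate decline is one closed form consistent with "initial
  rate 0.001, declining with epoch"; it is configuration, not a claim.
* Lap technique assignment assumes a block is dominated by one stroke;
  genuinely mixed medley *within a single lap* would need finer rules.
* The simulator's realism caveats above apply to every synthetic result.
* Training determinism is guaranteed only single-threaded; multi-threaded
  BLAS may reorder reductions.
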