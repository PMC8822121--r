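---
title: "Multimodal grasp-type recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal grasp-type recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pattern-recognition myoelectric control decodes the grasp a prosthesis user
intends to perform from surface electromyography (sEMG) of the remnant
forearm musculature. Classification from sEMG alone is brittle in daily-life
conditions. This package implements a multimodal strategy that exploits
natural eye-hand coordination: people briefly fixate the object they are
about to grasp, so a wearable eye tracker plus an egocentric object detector
can tell the controller *which object* is being targeted — and therefore
which grasp types are plausible — without any extra effort from the user.

Three components cooperate:

1. a **continuously running ConvLSTM classifier** over sEMG windows that
   outputs an 11-class posterior (ten grasp types + rest) every 20 samples
   (~10 ms at 1926 Hz), serving simultaneously as intent detector (rest to
   non-rest transition) and grasp classifier;
2. a **gaze-object association** stage that, for each valid gaze sample,
   finds the detected object instance whose contour lies within 20 px of the
   gaze point (score-filtered at 0.8, person/background excluded);
3. a **fusion state machine** that, on intent detection, identifies the
   target as the last looked-at object in the previous 480 sEMG samples
   (~250 ms), searching forward up to 500 ms if needed, and then restricts
   the classifier's argmax to the grasp types paired with that object. The
   machine restarts as soon as a sample is classified as rest.

## The grasping protocol

The acquisition protocol pairs each of ten grasp types (medium wrap,
lateral, parallel extension, tripod grasp, power sphere, precision disk,
prismatic pinch, index finger extension, adducted thumb, prismatic four
finger) with exactly three of 18 household objects, so that every object
admits at least one grasp and most admit several. Each grasp is repeated 32
times — 12 static-seated, 12 static-standing and 8 dynamic repetitions —
yielding 320 rest-grasp-rest trials per subject. Repetitions are divided
into 4 folds of 8 per grasp (3 + 3 + 2 per condition, on distinct objects),
used in 4-fold cross-validation; the three training folds are further split
by drawing one repetition per condition per grasp into a 30-repetition
validation set (210 train / 30 validation at full scale).

The fold assignment of individual repetitions is not dictated by the
protocol description; `build_fold_partition()` assigns them round-robin
within each (grasp, condition, object) cell — the k-th repetition of a cell
goes to fold k — which is deterministic and guarantees the distinct-object
composition within every fold. For the dynamic condition, the generator uses
the first two of the grasp's three paired objects.

## The classifier

Architecture, exactly as configured by `model_spec()`:

ConvLSTM (128 filters, 1 x 3 kernel) -> dropout 0.5 -> flatten ->
dense 200 (ReLU) -> dense 50 (ReLU) -> dropout 0.2 -> dense 11 (softmax),
trained with class-weighted categorical cross-entropy and Adam at default
parameters (learning rate 1e-3) for a fixed budget of 150 epochs with batch
size 32, keeping the parameter snapshot with the highest validation
accuracy. Class weights are balanced inverse frequencies,
`N / (K * n_c)`, which down-weight the predominant rest class.

Input windows are 200 samples (~104 ms) of standardized, rectified sEMG cut
without overlap; each window is divided into 10 subsequences of 1 x 20 x 12
(rows x columns x electrodes), giving the N x 10 x 1 x 20 x 12 input
tensor. The recurrence runs over the 10 subsequences; the 1 x 3 kernel
convolves along the 20-column (time-within-subsequence) axis with the 12
electrodes as channels. Implementation notes:

* The network is implemented directly in R (im2col + BLAS matrix products
  for both input-to-state and state-to-state convolutions, full
  backpropagation through time, Adam, inverted dropout). Same-padding is
  used along the 20-column axis so the spatial size — and hence the
  recurrent state — stays 20 throughout; the flattened feature is
  20 x filters.
* Initialization is Glorot-uniform with the forget-gate bias at 1, seeded;
  identical seeds give bit-identical models, and shuffling/dropout draws are
  seeded from `train_config(seed = )`.
* Streaming inference (`predict_stream()`) classifies the *trailing*
  200-sample window ending at the emission sample — the causal choice a
  real-time controller needs — and is bit-identical to batch inference on
  the same extracted windows.
* Validation accuracy is computed per window. Whether the original
  evaluation was per window or per repetition is not stated; per window is
  the implemented (and documented) choice.

Preprocessing is deliberately minimal — there is no feature-extraction
step. The scaler (per-channel mean/sd) is fit on training data only;
transformation is `|(x - mean)/sd|`, i.e. standardize **then** rectify, in
that printed order. Windows with mixed labels take the majority label, with
ties broken toward rest, which is conservative for intent detection.

## Gaze-object association

Detections are filtered to score >= 0.8 (a score of exactly 0.8 is kept:
"lower than 0.8" is discarded) with person/background always excluded. The
gaze-to-contour distance is the Euclidean distance to the polygon boundary;
a gaze point strictly inside a contour counts as distance 0 (being *on* the
object is the strongest looking-at evidence). The alternative reading —
distance to the boundary polyline even from inside — is available via
`gaze_config(inside_zero = FALSE)`. An object is looked at when the
distance is strictly below 20 px; equidistant instances break ties by lower
instance index. Each 100 Hz gaze sample maps to the 25 FPS frame whose
interval contains its timestamp (floor to the last started frame).
Annotation is restricted to the extraction window from 2 s before to 3.5 s
after each ground-truth grasp onset, mirroring how detector output is
stored offline.

## Fusion timing and semantics

All timing constants live in `fusion_config()`: 480-sample lookback counted
on the 1926 Hz sEMG clock (~250 ms), 500 ms forward timeout
(`ceiling(0.5 * 1926)` = 963 samples = 49 strides), stride 20. Decisions
made where the description leaves room:

* During the forward search (object not yet found, timeout not reached) the
  per-step output is the unimodal decision; fusion applies from the step at
  which the identification becomes available.
* A stream that starts non-rest counts as an intent event — necessary
  because extraction windows may clip the rest lead-in.
* The reset is exactly "as soon as a sample is classified as rest"; a
  `rest_debounce` parameter exists for multi-step release experiments but
  defaults to 1.
* Pre-identification steps of an episode are *not* re-labelled once the
  object is found (forward-causal semantics); an offline analysis that
  back-fills them would score slightly differently.

Two independent drivers — an offline replay and a step-incremental streaming
loop — implement these semantics and are asserted identical in the tests.

Two structural properties follow from the pairing table and are tested
deterministically: restriction can never demote a correct decision when the
identified object is correct (the true grasp is always in the allowed set),
and when the identified object is *not* paired with the true grasp, every
fused decision in the FUSED state is necessarily wrong — the approach's
guaranteed failure mode.

## The synthetic generator

`generate_subject()` emulates the protocol's structure, not sEMG
physiology: the aim is to make the pipeline's contracts testable.

* **sEMG**: rest is zero-mean Gaussian noise (sd 0.2, multiplied by 1.5 for
  the amputee population — a variability knob, no claim of realism); each
  grasp adds a fixed 10 x 12 nonnegative activation signature (smooth
  two-bump profiles across the electrode ring, pairwise distinct) under a
  raised-cosine envelope with 150 ms ramps and lognormal per-repetition
  amplitude jitter (sd 0.08). Rest durations are uniform on [1, 3] s (the
  protocol fixes only the 1 s minimum; 3 s is the package's choice), grasp
  holds uniform on [1.5, 2.5] s.
* **Scenes**: a 1920 x 1080 px frame (origin top-left, y down) holding the
  target plus at least four distractors as non-overlapping star-shaped
  simple polygons of 8-16 vertices placed on a jittered grid; an occasional
  person instance exercises the class filter.
* **Gaze**: scanning behaviour dwells ~300 ms on random scene objects;
  from 1 s before onset (`fixation_lead`) until 0.5 s after
  (`fixation_hold`) gaze fixates the target with 3 px jitter; invalid
  samples are injected at 2%.
* **Detections**: stored only within the extraction windows; scores are
  N(0.95, 0.03) clipped to [0, 1], instances are missed at 5% per frame,
  contours jitter by 1.5 px per vertex, and spurious instances appear at 2%
  per frame. `target_miss_prob = 1` produces the degenerate
  never-detected-target condition; `adversarial_fixation = TRUE` makes gaze
  fixate an object not paired with the true grasp.

What passing tests on this generator do **not** show: robustness to real
sEMG nonstationarity (fatigue, electrode shift, limb position), real
saccade/fixation dynamics, detector confusions between visually similar
objects, or video-level effects. They do show that the protocol accounting,
preprocessing layout, classifier training loop, geometric association, and
the fusion state machine behave exactly as specified on data whose ground
truth is known by construction.

## Numerical choices and degenerate inputs

* Exact nonparametric nulls are used for n <= 25 without ties (signed-rank)
  and pooled n <= 50 without ties (Mann-Whitney); otherwise the normal
  approximation with continuity (and tie) correction. Zero differences are
  dropped before the signed-rank test; all-zero differences are an error.
  Effect sizes are the matched rank-biserial `(W+ - W-)/(W+ + W-)` and the
  rank-biserial `1 - 2U/(n_a n_b)`, reported as magnitudes.
* Segments shorter than one window yield an empty windowing result with a
  warning; constant channels make the scaler error; degenerate polygons
  (< 3 finite vertices) error; an empty allowed-grasp set errors (the
  pairing table guarantees it cannot occur).
* Accuracy counts every classification step in the extraction window,
  including rest-labelled steps, over all 11 classes. Fold accuracies are
  averaged as per-fold percentages (not step-weighted).
* Probability rows are normalized by a numerically stable softmax; the
  tests assert row sums within 1e-6.

## Problem sizes used in tests

Headline accuracies from the original study require the real dataset
(15 amputees + 30 able-bodied subjects, full 150-epoch trainings) and are
out of scope here. The shipped tests and the acceptance script instead use:

* the **full ten-grasp protocol** (default configuration) for all structural
  counts — 320 segments, 4 x 80 folds, 210/30 split;
* a **miniature protocol** for everything that needs training: grasps 8 and
  10 (index finger extension, prismatic four finger), whose paired objects
  span exactly four classes (remote, knife, fork, wrench), with the full
  32-repetition fold structure, shortened rests (1-1.6 s), clean detections,
  a 16-filter ConvLSTM and 8 epochs. Held-out window accuracy is 96-98%
  across seeds; correct-object identification is 100% under clean fixations,
  0% when the target is never detected, and fused decisions are 0% correct
  under adversarial fixations, as the theory predicts.

## Known limitations

* The MATLAB-container adapter for the real public dataset is not included;
  the `read_bundle()`/`write_bundle()` text format is the ingestion surface.
  A user adapter needs to supply: the 12-channel sEMG matrix with per-sample
  (relabeled) grasp ids, gaze (t, x, y, valid), per-frame instances with
  class/score/contour, and the trial table with onsets and fold ids.
  Subject exclusions (e.g. unusable eye tracking) belong in that adapter.
* The generator's dynamic condition models only the gaze shift away from
  the target after onset, not post-grasp object manipulation kinematics;
  the gaze-shift timing is a parameter (`fixation_hold`) rather than a
  literature-calibrated value.
* Training is single-threaded; the default 128-filter, 150-epoch
  configuration is faithful but slow in pure R — scale `model_spec()` and
  `train_config()` to the problem at hand.
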