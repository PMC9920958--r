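---
title: "Skeleton-sequence activity recognition: model, tokenization and GAN rebalancing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-sequence activity recognition: model, tokenization and GAN rebalancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Falls are among the most dangerous events for elderly people living alone,
and camera-based monitoring is attractive because it requires no wearable
device. A practical recognition pipeline runs a pose estimator over the
video and keeps only the estimated body skeleton: 17 COCO joints per frame,
each an `(x, y)` pixel coordinate plus a detection confidence score, i.e.
51 numeric attributes per frame. `skelseq` implements the downstream
analysis: turning labeled skeleton streams into classification windows,
classifying them with a transformer encoder over *numeric tokens*, and
correcting the severe class imbalance that fall datasets always exhibit
(fall frames are rare by construction) with a conditional tabular GAN.

The package is organised around two fitted objects in the classic R
modelling idiom — `pose_transformer()` and `tabular_gan()`, each with
`print`/`summary`/`predict`-or-`simulate` methods — plus functional stages
(`build_windows()`, `fit_scaler()`, `run_experiment()`) that chain them.

## Windowing

A sliding window spans 2 seconds — 36 frames at the 18 fps of the target
recordings. To keep feature vectors small only three frames of each window
are retained (first, middle, last; 0-based offsets 0/17/35, where 17 is
`floor((36-1)/2)` for the even-length window), giving 3 × 51 = 153
features per window. The stride is configurable and defaults to 1 frame;
windows overlapping a frame with no usable detection are dropped (an
optional last-observation-carried-forward mode imputes them instead,
because silently fabricating poses is the wrong default). The window label
is the majority frame label, ties resolved to the last frame's label —
sensible for transition windows, where the later activity is the one the
window ends in.

## Numeric tokenization

A transformer encoder consumes sequences of integer token ids. Continuous
features are mapped onto a numeric vocabulary by global min–max scaling:

$$\mathrm{id}(F) = \left\lfloor V \cdot \frac{F - F_{\min}}{F_{\max} - F_{\min}} \right\rfloor$$

with **one scalar** $F_{\min}$/$F_{\max}$ pair for the whole table — not
per-feature scaling — and $V = 30{,}000$, so ids span 0…30,000. Values
outside the fitted range (possible when the scaler is fitted on the
training split only, the default; `fit_scope = "all"` reproduces
whole-dataset fitting) are clamped to the boundary first. The mapping is
monotone, and values more than one bin width apart always receive distinct
ids. Because the id for $F_{\max}$ is exactly $V$, the numeric ids number
$V + 1$; `[PAD]`, `[CLS]` and `[SEP]` follow at $V+1 \ldots V+3$ in the
from-scratch embedding table. Each window becomes
`[CLS] id_1 … id_153 [SEP]` — 155 tokens, comfortably inside the
512-token limit, with an all-ones attention mask (no padding is ever
needed at fixed length).

One property of this scheme matters for small-data work: token embeddings
are *learned per id*, so neighbouring ids share nothing until training
ties them together. With the full vocabulary and desk-scale datasets
almost every id occurs once and the embedding table cannot generalise.
Desk-scale runs therefore use a smaller numeric vocabulary (256 in the
package's benchmarks) so each id recurs across windows; the tokenizer's
default stays at 30,000, which is appropriate at the hundreds-of-thousands-
of-windows scale the method targets.

## The classifier

`pose_transformer()` trains a from-scratch transformer encoder: learned
token + position embeddings (layer-normed), post-norm encoder layers
(multi-head self-attention, GELU feed-forward, residuals), and a
classification head — dropout (p = 0.1) then a linear map — over the
final-layer `[CLS]` embedding. The `"base"` preset is the standard full-size
configuration (12 layers, 768 hidden, 12 heads; ≈110M parameters), kept
for full-scale runs; descriptions of this encoder sometimes mix its
dimensions up (768 hidden units in one breath, 512 and 8 heads in the
next), and we pin it to the standard base shape. Every test and benchmark uses the
`"tiny"` preset (2 layers, 64 hidden, 4 heads, 128 ffn), which trains in
minutes on one CPU.

Training follows the published recipe — AdamW, batch 16, 20 epochs,
70/15/15 stratified split — with one caveat: the 2e-5 default learning
rate is a *fine-tuning* setting. Training the tiny preset from scratch
uses 1e-3 (set explicitly in the benchmarks). Model selection keeps the
epoch with the best validation macro-F1. Attention-internal dropout is 0,
so evaluation is bit-deterministic and seeded training reproduces weights
exactly on one device. Class weighting of the loss exists but defaults
off: the package's remedy for imbalance is augmentation, and mixing the
two would confound the comparison the package exists to make.

`split_dataset()` offers `"window_random"` (the published protocol) and
`"grouped_by_source"`. With stride-1 windows, adjacent windows share
almost all frames, so random splits leak heavily across partitions;
grouping by recording prevents that. The benchmark sidesteps the issue by
generating non-overlapping windows (see below).

## Mode-specific normalisation and the conditional GAN

`tabular_gan()` follows the conditional tabular GAN recipe. Each of the
153 continuous columns is normalised by a Gaussian mixture fitted with
variational Bayesian inference (k = 10 components, Dirichlet +
Normal–Gamma priors): a value becomes a one-hot *mode* plus a scalar
`alpha = (x − µ)/(4σ)` clipped to [−1, 1]. Overlapping components — a
variational fit tiles a broad unimodal density with several overlapping
Gaussians — are moment-matched and merged when their means lie within 2
standard deviations, which both recovers unimodal parameters exactly and
keeps the encoded row compact; truly multi-modal columns keep their
modes. Constant columns degenerate to one mode with a floored σ (1e-6 of
the column range) so decoding still round-trips.

Generator and discriminator are two-hidden-layer fully connected nets
(widths 256 by default). The generator receives Gaussian noise plus the
one-hot class condition and emits, per column, a tanh `alpha` and a
softmax over modes, plus a softmax over class labels; an auxiliary
cross-entropy pushes the generated class to match the condition, and the
label is additionally enforced at decode time, so conditional integrity
is exact. The discriminator scores *packs* of rows jointly (8 by default; packed
discrimination): judging samples in groups lets it detect collapsed
diversity, and in our experiments this was the difference between
generated standard deviations at ~0.6× the real ones and ~1.0×.
Conditions are drawn by training-by-sampling from the empirical class
frequencies (the published behaviour); a `log_frequency` switch flattens
the draw towards rare classes, which is the appropriate setting when the
entire point is to synthesise classes holding <1% of the rows. An
optional pairwise feature-matching penalty (off by default) pulls each
generated row toward its condition-matched real partner; with seven
conditions backed by only ~10 real rows each, the adversarial signal
alone left conditional means collapsed onto the majority class, and this
penalty is what anchors them — at a deliberate cost in within-class
diversity, acceptable for augmentation.

`build_plan()` decides how many synthetic rows each class receives:
`"published"` reproduces the published per-class counts for the UP-Fall
window table (84,065 rows over seven minority classes, ≈40% growth);
`"target_share"` raises each minority class to a requested share of the
final dataset, solved jointly by fixed-point iteration (with a
feasibility check — you cannot raise 12 classes to 10% each). Synthetic
rows are added to the *training* partition only; validation and test
stay purely real, which is the only arrangement under which the
balanced-vs-unbalanced comparison means anything.

## Synthetic motion data

Real fall datasets cannot ship with a package, so `generate_dataset()`
emulates labeled 17-joint trajectories: a posture template plus per-class
analytic kinematics — periodic limb swing and horizontal drift for
walking, a crouch cycle for picking up an object, vertical bounce for
jumping, small sway for standing/sitting/laying, a drifting posture for
the unknown class, and for the five fall classes a smooth ~1-second
descent from upright into a lying pose, with per-class trajectory shape
(hands-first arc, two-phase knee fall, backward, sideways, onto a chair).
Falls deliberately end in the laying posture: that falls get confused
with lying down is exactly the error structure reported for real data,
and it is what makes under-represented fall classes genuinely hard.
Detection scores are drawn uniformly in [0.5, 1] and carry no class
signal. Per-sequence anchor position (a ±64 px band, the working area of
a fixed-camera laboratory recording), movement phase and left/right
orientation are randomised (`jitter = FALSE` disables this; with noise
near 0 the classes are then trivially nearest-centroid separable, a
property the tests verify). Gaussian pixel noise controls difficulty; the
default SD of 4 px against a ~170 px figure corresponds to the keypoint
jitter of a good pose estimator at 480p (roughly 0.5–1% of image
height) while keeping the archetypes separable, which the classifier
contract requires of this generator.

`imbalance_profile("upfall_like", budget)` reproduces the published class
shares of the 207,497-window table (walking/standing/sitting/laying
18–25% each, five fall classes and two further minorities below 1%) with
largest-remainder rounding, so the synthetic benchmark has the same
imbalance structure as the real dataset.

What the generator does *not* emulate: camera projection, occlusion,
pose-estimator failure modes (identity switches, missing limbs),
multi-person scenes, or biomechanically realistic dynamics. Passing
benchmarks on this data shows the pipeline's mechanics work end-to-end
and that augmentation corrects imbalance under controlled conditions; it
does not certify real-world fall-detection accuracy.

## The benchmark experiment

`run_experiment()` chains everything: generate → window → split → fit
scaler (train scope) → tokenize → optionally GAN-augment the training
rows → train → evaluate on the untouched real test windows, writing every
artifact plus a manifest (derived stage seeds, config hash, row counts,
test-split hash). `compare_arms()` refuses to compare runs whose test
splits differ (hash check) and reports macro deltas and per-class recall
deltas.

Problem sizes were chosen to make one full two-arm comparison run in
roughly twelve CPU-minutes: 1,600 windows on the `upfall_like` profile,
each sequence exactly one window long (2 s at 18 fps) so windows never
overlap and the random split cannot leak; numeric vocabulary 256; tiny
encoder, 12 epochs at lr 1e-3; GAN with 128-wide nets, 4-wide packs,
log-frequency condition sampling, feature matching on, and a 5% target
share (≈45% dataset growth, comparable to the published ≈40%).

One measurement choice needs spelling out. At this budget the sub-1%
classes hold ~11 windows each, so a 15% test split would contain one or
two windows per minority class and per-class recall deltas would be coin
flips. The benchmark therefore trains and validates on the imbalanced
data (85/15 split — the imbalance is the condition under study) but
evaluates both arms on a *shared generator-held-out, class-balanced set*
of 25 windows per class (`run_experiment(test_sequences = …)`), the way
one would evaluate against an external test recording. Under these
conditions the plain arm learns the majority classes and largely misses
the sub-1% classes, and the augmented arm recovers a substantial part of
the minority recall while keeping the majorities — the same qualitative
finding, with the same signs on every macro metric, as the published
full-scale comparison. A characteristic detail: without augmentation the
model lumps all five fall subtypes into one, so one fall class shows
decent recall and its four siblings none; augmentation spreads them back
out. The acceptance suite asserts the directional result, not any
headline percentage: the published numbers (99%+ macro accuracy) come
from 207k real windows and a pretrained 110M-parameter encoder, which a
desk-scale synthetic run cannot and should not be tuned to reproduce.

## Numerical and design notes

- Gradients for the encoder and both GAN nets are hand-derived; a
  finite-difference check over every parameter group is part of the
  development harness. The attention inner loop is compiled (Rcpp +
  Armadillo); its backward pass recomputes the softmax rather than
  caching the L×L probability matrices, trading ~20% extra attention
  flops for far less heap traffic.
- AdamW weight decay (0.01) applies to weight matrices only, never to
  biases, layer norms or embeddings; embedding gradients are applied
  lazily (only rows touched by a batch), which is exact for the moment
  estimates of touched rows and standard practice for sparse updates.
- Ties: argmax prediction breaks ties toward the lower class id; majority
  labels break toward the last frame; multi-detection frames break toward
  the first record at equal mean score. All are asserted in tests.
- One-vs-rest metric ratios with zero denominators are reported as 0 and
  flagged rather than NaN, so macro averages stay defined; per-class
  "accuracy" is one-vs-rest accuracy, and macro averages are unweighted.
- `derive_seed()` fans a single run seed into per-stage seeds (all below
  2^31), so any stage can be re-run in isolation.

## Limitations

- The from-scratch encoder at desk scale is *not* the pretrained
  fine-tuned model: no pretrained weights are shipped or loaded, so
  absolute accuracies are not comparable to published full-scale results.
- Global scalar min–max tokenization couples all features to one range;
  columns with small dynamic range (confidence scores in [0, 1] against
  pixel coordinates in [0, 640]) occupy few distinct ids. That is the
  method as specified, faithfully implemented, and its resolution limits
  are inherent.
- The GAN learns minority classes from very few rows at desk scale;
  packed discrimination and log-frequency sampling make this workable,
  but generated minority rows are best understood as smoothed resamples,
  not new information.
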