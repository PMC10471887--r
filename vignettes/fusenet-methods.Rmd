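---
title: "Dual-branch feature fusion for histopathology patches: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch feature fusion for histopathology patches: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fusenet)
```

## The problem and the model

Bile-duct (cholangiocarcinoma) histology scenes are large H&E-stained RGB
fields of view in which cancer regions range from small islands to the whole
frame. `fusenet` implements a two-pathway convolutional classifier for the
benign/malignant decision: a residual **spatial branch** (five stages,
channels 32–512, stride-2 first structure per stage) extracts deep spatial
features, while a **channel branch** — a multiscale convolution stem (MSF)
and a stack of multilevel 1×1-convolution blocks (MLF) with feature reuse —
extracts channel statistics of the stain mixture at several receptive-field
sizes. The branch outputs are merged by element-wise summation at the unique
depth where their shapes coincide, and a 1024-channel convolutional head with
global average pooling produces the two logits.

Assumptions worth making explicit:

- Scenes are single-label (the whole field of view is benign or malignant);
  there is no segmentation or localization.
- The two cancer-bearing scene categories (partial and full coverage) are
  merged into one malignant class. With the reference composition
  (690 + 48 vs 142 scenes) this leaves a ~5.2 : 1 class imbalance, which is
  why sensitivity and specificity are reported separately.
- All fusion points are *sums*, not concatenations. This is forced by the
  published layer table: the stem's fused output keeps 64 channels and the
  post-fusion residual stage expects 256 input channels; concatenation would
  double both and also overshoot the printed parameter total.

## Reconciling the parameter total

The published table prints 20,949,378 trainable parameters but leaves the
micro-layout (bias yes/no per convolution, BN on the shortcut, BN on the
head) unstated, and no assignment of biases that is uniform across the whole
network reproduces the number. The unique natural configuration that matches
it **exactly** is:

| part | conv bias | BN |
|---|---|---|
| residual branch (incl. 1×1 projection shortcuts) | no | yes |
| channel branch (MSF, MLF) | yes | yes |
| head convolution | yes | yes |
| fully connected layer | bias | — |

giving 15,900,288 + 325,376 + 4,723,714 = 20,949,378. This split mirrors how
such models are typically assembled in practice: residual blocks copied from
a torchvision-style implementation (`bias = FALSE` convention) and custom
modules left at the framework default (`bias = TRUE`). The builder's
per-unit accounting and an independent closed-form oracle are compared in
the test suite across every variant.

Two more table-versus-prose conflicts are resolved in the table's favour:

- The MLF trailing max-pool is described with stride 1 but must halve the
  spatial dimensions per the table (and "dimensionally reduces"); it is a
  3×3 / stride 2 / padding 1 pool here.
- The MLF's fourth convolution is described as channel-doubling, but the
  first block maps 64→64 in the table; doubling starts at the second block
  (64, 128, 256, and 512 when a fourth block is configured).

Activation placement follows the stated "BN after the convolution, before
the activation", with the residual addition placed before the block's final
ReLU (the standard residual ordering). Fusion sums combine already-activated
maps and add no extra nonlinearity; a practical consequence is that the
stem's fused output equals the element-wise sum of its four captured path
outputs exactly, which the visualization tests exploit.

## Preprocessing conventions

- Short-edge resize uses **floor** for the long edge: 2304·512/1728 = 682.67
  truncates to 682, matching the printed 682×512. Round-half-up would give
  683.
- Bilinear interpolation without antialiasing (the EBImage backend behind
  the module surface); resizing is skipped entirely (bit-identical) when the
  short edge is already at target.
- Center crop offsets are `floor((dim − size)/2)` with 0-based, half-open,
  top-left-origin indexing; no padding — an oversized crop is an error.
- Standardization is `(p/255 − mean_c)/std_c`. The reference work never
  states its constants; the package's convention is to compute them from the
  training split of the active fold (`channel_stats()`), with explicit
  overrides available.
- The default strategy is 512-448, consistent with the published layer
  table; the alternative 256-224, 384-336 and 640-560 strategies are plain
  configuration values. (The prose elsewhere selects 384-336 on
  cost/accuracy grounds; which one produced the headline numbers is
  ambiguous, so the table's configuration wins the default.)

## Training protocol

SGD with learning rate 0.001, momentum 0.9, weight decay 1e-6 (reading
"decay of weights dropping to 1e-6" as the standard weight-decay
coefficient), batch 16, cross-entropy over the two logits, no schedule, no
augmentation, no early stopping. The incomplete final batch is kept.
Checkpoint selection keeps the epoch with the highest **training** accuracy,
earliest epoch on ties — exactly as specified, despite the overfitting risk;
the epoch accuracy is accumulated over the epoch's minibatches as training
proceeds.

Folds are stratified by label: each class is shuffled (seeded) and dealt
round-robin, so per-fold class counts deviate from proportionality by at
most one scene (benign test folds of 28–29 under the reference
composition — the published per-fold table is only achievable by splitting
scenes, not patients, so scene-level splitting is the default). Because
scene-level splitting can place one patient's scenes in both train and test
folds, a `grouping = "patient"` mode keeps patients intact (greedy balanced
assignment within each class); it is off by default for fidelity and its
leakage implications are the user's to weigh.

One deliberate behavioural note: with a zero learning rate the weights are
bit-frozen, but per-epoch accuracies can still differ across epochs when
there is more than one minibatch, because batch-normalization statistics
depend on batch composition and the composition is reshuffled each epoch.
With a single batch per epoch the history is exactly constant.

## Evaluation

Malignant is the positive class (sensitivity = malignant recall), the
malignant score is the softmax probability of the malignant logit, and AUC
is the trapezoidal area under the ROC built from grouped score thresholds —
algebraically the Mann–Whitney statistic with ties counted ½, which the test
suite verifies against both a pairwise oracle and an external reference
implementation to 1e-12. Macro F1 is the unweighted mean of the per-class F1
scores. Degenerate folds report undefined metrics as `NA` with a warning,
never as 0. Since the aggregation rule behind the published single numbers
is unstated, both mean-of-folds and pooled-predictions modes are emitted,
clearly labelled; mean-of-folds is the headline.

## The synthetic generator

Real bile-duct histology cannot be redistributed, so the generator emulates
only the *statistical skeleton* the pipeline needs: eosin-pink multi-octave
value-noise backgrounds; sparse low-contrast purple blobs in every scene;
and a dense hematoxylin-purple cluster covering 20–60% of partial-cancer
scenes and ≥ 90% of full-cancer scenes. The `separability` dial scales the
cluster tint linearly: at 0 all categories are drawn from identical blob
parameters (class-conditional intensities coincide); at 1 a one-feature
threshold on mean green intensity separates the classes almost perfectly
(AUC ≥ 0.95 over 100 scenes per class, checked in the tests). Default image
size is 576×432 — one quarter of the native 2304×1728 — purely to keep
generation fast; full size is a configuration value. Patients are assigned
round-robin within a category and never straddle categories; the real
per-patient scene distribution is unknown, so it is uniform here. Each scene
draws from an RNG stream derived by hashing (dataset seed, scene id), so
generation order can never change content and regeneration is byte-identical.

What the generator does **not** emulate: nuclear morphology, stain
deconvolution physics, scanner noise, inter-patient texture correlation, or
hyperspectral channels. Passing tests on synthetic data therefore
demonstrate that the architecture, optimizer, cross-validation harness and
metrics behave correctly — not that the model reaches any particular
accuracy on real tissue.

## Numerical choices

- Batch normalization: eps 1e-5, running-statistics momentum 0.1, biased
  variance for normalization, unbiased for the running estimate; evaluation
  mode uses the running statistics.
- Initialization: Kaiming fan-out normal for convolution kernels, unit
  scale/zero shift for BN, uniform ±1/√fan-in for the fully connected layer;
  all seeded, and every derived seed stays below 2^31.
- The engine is plain double precision over im2col + BLAS gemm with
  hand-derived backward passes; gradients are validated against central
  finite differences on every unit type (probe step 1e-7 — large steps can
  straddle ReLU/max-pool kinks, the one place the two estimates legitimately
  part, and BN's curvature at near-degenerate 1×1 maps makes coarse probes
  unreliable even when the analytic gradient is exact).
- Max-pool ties break toward the first tap in scan order; padding is treated
  as −∞ (never selected).
- Determinism: all stochastic steps (generation, folds, initialization,
  shuffling) flow from explicit integer seeds through a per-purpose
  derivation hash; two runs with one seed are byte-identical, which the
  acceptance suite asserts end to end.

## Desk-scale problem sizes

The test and acceptance runs use deliberately small instances chosen once:
synthetic scenes at 32–64 px for training exercises and 48 px for generator
statistics; the scaled-down learning comparison uses 40 fully separable
training scenes (20 benign / 16 partial / 4 full), a disjoint 20-scene
held-out set, 15 epochs, batch 16, and compares the full model against the
spatial-only ablation over five seeds, asserting only the *direction* (full
not worse on held-out AUC) plus near-perfect training accuracy. The
published-scale accuracies require the original database and ~200-epoch
training and are out of scope as numeric targets.

## Known limitations

- Training-accuracy checkpoint selection will overfit on hard data; the
  validation-style alternative is patient-grouped folds plus the pooled
  report, but the faithful default makes no such correction.
- The synthetic task is far easier than real histology; directional
  comparisons between variants on it are meaningful, magnitudes are not.
- Single-threaded CPU engine: practical for the desk-scale instances here,
  not for 448×448 inputs at hundreds of epochs.
- The 30-channel hyperspectral variant of the source collection, the
  off-the-shelf baseline architectures, and attention/recurrent extensions
  are out of scope.
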