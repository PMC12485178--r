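---
title: "Multi-scale self-supervised pretraining for fundus grading: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale self-supervised pretraining for fundus grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diabetic-retinopathy (DR) grading assigns a color fundus photograph one of
five ordinal severity stages (0 = no disease ... 4 = proliferative). Labeled
fundus data are scarce and transfer from natural-image corpora is unreliable,
which motivates self-supervised pretraining directly on fundus photographs:
learn a representation from unlabeled retinal images, then attach a small
classifier.

`msssl` implements a momentum-encoder self-supervised framework specialized
for this domain. Its encoder fuses two complementary views of each image:

* a **global branch (GFE)** — a vision transformer over non-overlapping
  patches whose self-attention captures image-wide context;
* a **fine-grained branch (FFE)** — a ResNet trunk with a feature-pyramid
  network (FPN) exposing the P2/P3/P5 levels (strides 4/8/32), which carry
  the small, local structure (microaneurysm- and exudate-scale detail) that
  grading depends on.

P3 and P5 are bilinearly upsampled to the P2 grid and concatenated; the ViT
patch tokens (global token excluded) are projected with a 1×1 linear map and
resized to the same grid; the two stacks are combined by elementwise
addition (channel concatenation and elementwise multiplication are kept as
configurable alternatives). A **Deep Learner (DLe)** refines the fused map
through stride-2 transposed convolutions (kernel 3, padding 1, output
padding 1 — each stage exactly doubles the side) with rectifier
nonlinearities, ending in a convolutional block attention module (CBAM). A
1×1 convolution on the DLe output, resized to image resolution, provides
segmentation logits.

# The pretraining objectives

Two losses are summed, `total = match + lambda_seg * seg` (an exact identity
maintained in every `loss_report`):

**Representation matching (self-distillation).** A momentum teacher — an
exponential-moving-average copy of the student,
`t <- m t + (1 - m) s` with `m = 0.996` — processes each augmented view and
produces a projection. Its distribution
`softmax((teacher - center) / tau_t)` with the sharper temperature
`tau_t = 0.04` is the (gradient-free) target for the student distribution
`softmax(student / tau_s)` with `tau_s = 0.1`, scored by cross-entropy and
symmetrized over the two views (teacher on view A targets student on view
B and vice versa). The running `center` (EMA of teacher projections,
momentum 0.9) prevents collapse onto a single logit. No negative pairs are
used anywhere: per-sample losses never compare across batch elements, a
property the test suite asserts literally by duplicating a batch element.

The matching family leaves the exact loss open; the centered,
temperature-sharpened cross-entropy form was chosen because it is the
canonical negative-free objective of the momentum-encoder family and
pairs naturally with the global-token attention analysis the package also
implements.

**Saliency segmentation.** Each image's green channel is passed through a
saliency detector, binarized by Otsu's method, and the resulting mask —
transformed with exactly the geometric parameters of each augmented view —
is the ground truth for the DLe segmentation head: pixel-wise binary
cross-entropy (stable logits form) plus soft Dice with smoothing
`eps = 1`, equal weights, averaged over views. This auxiliary task forces
the high-resolution pathway to retain subtle local structure that a pure
instance-level objective would discard. The saliency masks ride with the
teacher's input views, so the teacher's targets are computed on
salient-consistent crops; no input masking is applied (the guidance
mechanism is otherwise a free design choice, and loss-side supervision is
the least invasive).

# Preprocessing and augmentation

The **green channel** of an RGB fundus photograph carries the highest
lesion/vessel contrast, so the whole pipeline is green-channel based: the
plane is extracted, replicated to three identical channels (so standard
3-channel backbones apply unchanged), scaled to [0, 1] and standardized
(mean 0.5, sd 0.5 per channel by default). Dark borders are cropped by a
tight bounding box over pixels whose maximum channel value exceeds 10/255 —
a threshold robust to compression noise on nominally black frames.

Two saliency detectors are provided:

* **fine-grained** (default, the stronger setting): multi-radius
  center–surround contrast, `sum_r |g - boxmean_r(g)|` for radii 3, 7, 15,
  min–max normalized;
* **spectral**: the spectral-residual method — log-amplitude spectrum minus
  its 3×3 mean, recombined with the original phase, inverse-transformed,
  squared, Gaussian-smoothed, normalized.

Binarization uses Otsu's threshold over a 256-bin histogram (exhaustive
between-class-variance maximization; parameter-free and reproducible —
the rule itself is unstated upstream of this package, so the most standard
choice was taken). Constant maps yield all-zero masks rather than errors.

Augmentation follows the SimCLR recipe: random resized crop (area scale
0.3–1.0 — the lower bound is raised from SimCLR's 0.08 because the retinal
disc occupies the frame center and extreme crops would sample pure
background), horizontal flip with probability 0.5, color jitter
(brightness/contrast/saturation 0.4, hue 0.1), Gaussian blur with a random
odd kernel applied with probability 0.5, then standardization. Both views
draw from the same augmentation distribution. Geometric parameters are
replayed on the mask (nearest-neighbor resize keeps it binary); photometric
operations skip it.

# Numerical implementation

No deep-learning runtime exists in this package's dependency footprint, so
the networks, reverse-mode automatic differentiation, and the
decoupled-weight-decay adaptive optimizer (cosine schedule, base learning
rate 5e-4, warmup 10 steps) are implemented in R with
C++ (Armadillo) kernels for the im2col/col2im convolutions, transposed
convolutions, max-pooling and normalization statistics. Every layer's
backward pass is validated against central finite differences in the test
suite; the composite blocks (CBAM, fused encoder, both losses) are
additionally checked against explicit loop-based oracles.

Normalization inside the ResNet trunk is **group normalization**
(per-sample, per-group, ~8 channels per group) rather than classic batch
normalization: batch statistics would couple batch elements, violating the
framework's guarantee that one sample's loss is independent of the rest of
the batch (and making linear-probe features depend on batch composition).
The ViT uses standard per-token layer normalization; GELU in the MLPs and
projection head; exact (not tanh-approximated) Gaussian CDF form.

Other numerical conventions worth knowing:

* bilinear resizing uses half-pixel centers with edge clamping; a constant
  field resizes to the same constant, and the backward pass is the exact
  transpose of the interpolation operator;
* the Deep Learner halves its channel count per stage with a floor of 32;
* the learning rate is the configured base rate, not batch-scaled: the
  common linear batch-scaling rule targets production batch sizes and
  degenerates at desk-scale batches, where it would make short pretraining
  runs vacuous;
* CBAM's channel attention uses reduction ratio 16 (inputs with fewer than
  16 channels are rejected), spatial attention a 7×7 convolution;
* Otsu ties break toward the lowest cut; `mask = value >= threshold`;
* min–max normalizations guard the constant case by returning zeros;
* ViT-S is 384-d/12-layer/6-head and ViT-B 768-d/12-layer/12-head (the
  standard recipes); patch sizes 16 and 32 are supported, and the learned
  position embedding is bilinearly interpolated when an image is evaluated
  at a different resolution (e.g. 1024 px attention maps);
* the fused map uses the ViT patch-token grid, not the pooled vector — a
  spatial map is required for the Deep Learner's upsampling to be
  meaningful; the projection head output feeds only the matching loss.

# Configuration

`load_config()` starts from the best-ablation defaults — fine-grained
saliency, ResNet50 FPN (`c_fpn = 256`), ViT-S patch 16 at 224 px, addition
fusion, two transposed-conv DLe stages with CBAM last — validates every
enum, and fingerprints the structural blocks (encoder/dle/preprocess) with
a digest stored in every checkpoint; evaluating a checkpoint under a
structurally different configuration is an error, never a silent coercion.
One root seed (`runtime.seed`) is fanned out to named substreams
(initialization, data order, augmentation, head training), which is what
makes full runs bit-exactly reproducible and checkpoints resumable
mid-epoch (the epoch's shuffled order is part of the checkpoint).

# Downstream protocols

Datasets are split 70/15/15 (train/validation/test) on unique image ids —
dual views of one eye never straddle a split — stratified by grade by
default (plain random splitting is what the protocol upstream states;
stratification was turned on because it stabilizes small benchmarks and is
exposed as a flag). Rounded fractions assign the remainder to train.

**Linear evaluation** freezes the encoder (asserted by checksum before and
after) and trains a single linear softmax layer on the pooled
representation, full-batch, selecting the epoch by validation quadratic
weighted kappa — kappa because it is the standard ordinal-grading metric
and the one emphasized throughout this line of work. **Fine-tuning** opens
the global branch and the same linear head to gradients; with zero epochs
it degenerates to evaluating the initialized head, a contract the tests
pin down.

The **pooled representation** is, by default, the spatially averaged Deep
Learner output of the full multi-scale path (`eval.head = "full"`). This
was a genuinely open design point; the package resolves it in favor of the
full path because the multi-scale encoder *is* the pretrained
representation — a linear layer on its pooled output adds no downstream
model complexity — and because the fine-grained branch is the component
designed to carry lesion-scale information. At desk scale the choice is
not cosmetic: a 64-px ViT with 16-px patches sees a 4×4 token grid and
cannot resolve 2–3 px lesions, whereas the stride-4 pyramid can. The
global-token alternative remains available as `eval.head = "gfe"`.

`linear_eval()` can also run a **label-permutation control**
(`null_permutations > 0`): the train and validation labels are shuffled
jointly — validation included, because kappa-based model selection is part
of the fitting pipeline and would otherwise leak true grade structure into
the supposed null — and the mean test kappa over the permutations estimates
the no-information baseline. On the synthetic benchmark it sits at chance
while the real-label probe does not.

Metrics: quadratic weighted kappa
(`kappa = 1 - sum(w O) / sum(w E)`, `w_ij = (i-j)^2/(K-1)^2`, `E` the
scaled marginal product), accuracy, weighted/macro/micro F1 (micro-F1
equals accuracy in this single-label setting — asserted, not assumed), and
the full 5×5 confusion matrix.

**Attention maps** follow the self-distillation visualization practice:
resize to 1024 px, run the ViT, take the final layer's global-token row,
drop the self-entry (which keeps the grid square), average heads, min–max
normalize to the patch grid.

# The synthetic fundus generator

Real fundus corpora cannot ship with a package, so every protocol is
exercised on a generator that emulates the gross structure of a fundus
photograph: a bright circular retina (radius 0.92 of the half-width) on a
black frame, green-dominant coloration with radial shading, one elliptical
optic-disc highlight, a random-walk vessel tree darker than the retina, and
`N ~ Poisson(rate[grade])` lesions per image — dark dots or bright blobs
with probability 1/2 each, loosely mimicking hemorrhages versus exudates.
Default rates (0, 2, 5, 10, 20) increase strictly with grade so that a
lesion-count oracle separates grades; the benchmark used by the acceptance
checks uses the more separated (0, 4, 10, 18, 30). Dual-view pairs are the
same eye mirrored with independently drawn vessel noise, standing in for
two-field photography.

What the generator does **not** model — and therefore what passing tests do
and do not show: real lesion morphology, illumination artifacts, camera
vignetting, media opacity, inter-grader label noise. Results on this
benchmark demonstrate that the pipeline is wired correctly end to end
(representations recover a grade signal that is genuinely in the images;
label-shuffled controls land at chance), not that any accuracy level
transfers to clinical data.

# Desk-scale problem sizes

The bundled tests and the acceptance script run a reduced encoder chosen as
the smallest configuration that still exercises every architectural
component: 64-px inputs, a depth-2/64-d/4-head ViT (patch 16), a
width-16 resnet18 trunk under a 64-channel pyramid, two DLe stages, batch 8.
The training smoke test takes 50 optimizer steps on one fixed batch; the
representation-recovery benchmark pretrains 5 epochs on 300 synthetic
images (60 eyes per grade) and linear-probes a held-out split over three
seeds. The full-size defaults (ViT-S/224, ResNet50, 300-epoch schedules)
are expressed in configuration and run through exactly the same code paths.

# Known limitations

* The R/C++ training loop is single-process and CPU-oriented; it is meant
  for method study and desk-scale experiments, not for pretraining at
  photographic resolution.
* The teacher mirrors the student's full parameter set but only its ViT
  trunk and projection head are evaluated (only the projection output is
  consumed); its fine-grained branch exists solely to keep the EMA
  structure congruent.
* The `conv1d` Deep-Learner stage (an ablation-only path) runs its
  length-3 kernel over the flattened spatial axis per channel; the axis
  choice is a convention, as no canonical definition exists for 2-D maps.
* Group normalization in place of batch normalization changes optimization
  dynamics slightly relative to a classic ResNet; it was accepted to keep
  per-sample losses exactly batch-independent.
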