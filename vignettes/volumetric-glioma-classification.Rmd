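---
title: "Classifying glioma grade in volumetric MRI with residual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying glioma grade in volumetric MRI with residual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gliomas are graded by the WHO into low-grade (I–II) and high-grade (III–IV)
tumours, and the distinction drives treatment. On contrast-enhanced
T1-weighted MRI a high-grade tumour typically shows a necrotic
(hypointense) core surrounded by an actively enhancing (hyperintense) rim,
while low-grade lesions enhance more homogeneously; a healthy brain shows
neither. `resvol` implements a three-class volumetric classifier
(LGG / HGG / HEALTHY) for single-channel 3D volumes, built around the idea
of treating the slice axis of a volume as the pseudo-temporal axis of a
video-recognition network, so that factorized and mixed spatiotemporal
convolutions can be reused as "spatio-spatial" operators.

## The three architectures

All three networks share one skeleton: a stem, four stages of two residual
blocks with channel widths 64/128/256/512, identity-path downsampling
(kernel-1, stride-2 convolution plus batch-norm) at stages 2–4, adaptive
average pooling to 1×1×1 (512 features), dropout 0.3, and a fully
connected layer to `n` class logits. Every convolution is bias-free and is
followed by batch normalisation and ReLU; blocks use the standard
post-activation residual ordering conv→BN→ReLU→conv→BN, add, ReLU. Kernel
tuples are written (slice, row, col).

* **ResNet3D** — stem convolution kernel (3,7,7), stride (1,2,2), padding
  (1,3,3), 1→64 channels; all stage convolutions are full 3D kernels
  (3,3,3). 33,148,995 trainable parameters as built here (see below).
* **ResNet(2+1)D** — every 3D convolution is factorized into an in-plane
  (1,3,3) convolution to `M` intermediate channels, batch-norm, ReLU, then
  a slice-axis (3,1,1) convolution. `M` is chosen so the factorized pair
  has about as many weights as the full 3D kernel:
  `M = floor(27·in·out / (9·in + 3·out))` (`midplanes_2p1d()`); within a
  block `M` is computed once from the block's in→out channel pair and
  shared by both of its convolutions. The stem uses a (1,7,7) convolution
  1→45, then a (3,1,1) convolution 45→64, each with batch-norm + ReLU.
  31,297,254 parameters.
* **ResNet Mixed Convolution** — the 3D stem and a full-3D stage 1,
  followed by three in-plane 2D stages (kernels (1,3,3), downsampling
  stride (1,2,2)). With 11,472,963 parameters it is by far the lightest of
  the three.

Strided blocks carry the stride on their first convolution (on the 2D part
in-plane and the 1D part along slices for (2+1)D; in-plane only for the 2D
stages of the mixed model), with the kernel-1 convolution + batch-norm pair
on the identity path. A "stride of one everywhere" reading of the block
description cannot be reconciled with a stride-2 identity path, so the
reference video-network convention is used; parameter counts are unaffected
by strides.

`count_trainable_parameters()` reproduces the published totals exactly for
the mixed and (2+1)D models under these conventions. For ResNet3D our
strictly-as-described build totals 33,148,995, i.e. 0.0046% below the
published 33,150,522; the residual 1,527 parameters cannot be attributed
from the published description alone (they would correspond, e.g., to some
small stem or head variation). `architecture_summary()` emits the full
layer table — one row per convolution, batch-norm and linear layer with its
channel counts, kernel and parameter count — so the count is auditable
layer by layer.

## Objective

Class imbalance (the reference cohort has 73 LGG vs 259 HGG and 259
healthy volumes) is handled by weighting the cross-entropy loss with
normalised class weights

\[ W_c = 1 - \frac{samples_c}{samples_t}, \qquad
   loss_c = W_c\,[-x_c \log P(c)], \qquad
   Loss_{total} = \sum_c loss_c, \]

where \(x\) is the one-hot true distribution and \(P\) the softmax of the
logits. The weights always sum to \(n-1\). Weights are recomputed per fold
from the training split only, so no test information leaks into the loss.
Within a batch the loss (and its gradient) is the mean over samples; the
reference protocol uses batch size 1, where this choice is inert.

## Data pipeline

Volumes are read from NIfTI files with the axes in stored order interpreted
as (slice, row, col); a manifest CSV (`subject_id,path,label`) carries the
labels. Preprocessing is per-volume: intensities are clipped to the
[0.5, 99.5] percentile range computed over all voxels and mapped affinely
onto [0, 1], then the volume is resampled trilinearly to 2 mm isotropic
spacing with output extents `round_half_up(dim · spacing / target)`.
Three choices here were genuinely open and are fixed as follows:

* the percentile normalisation is clip-then-min-max; a clip-then-z-score
  variant is available via `percentile_clip_scale(method = "zscore")`;
* percentiles are computed per volume (not per dataset) and over all
  voxels, with no foreground masking;
* the resampled-grid rounding rule is round-half-up, chosen once so grids
  are reproducible (e.g. a 240×240×155 grid at 1 mm maps to 120×120×78).

Training-time ("light") augmentation is a random affine — isotropic scale
drawn from [0.9, 1.2] and per-axis rotations up to 10° about the volume
centre, resampled back onto the original grid with zero fill — followed by
a random left-right flip with probability 0.25. Augmentation is applied on
the fly during training only, with fresh draws per sample per epoch;
evaluation always sees unaugmented volumes. Heavier augmentation (elastic
deformation, k-space artefacts) is deliberately out of scope.

## Training and evaluation protocol

The dataset is split by 3 independent stratified random 70/30 train/test
splits (a 7:3 ratio per fold is not compatible with partitioning 3-fold
cross-validation, so independent repeats are the only consistent reading);
per class the test side receives `round_half_up(0.3 · n_c)` subjects — for
cohort sizes (73, 259, 259) that is (22, 78, 78). Each fold trains a fresh
network with Adam (defaults: learning rate 1e-5, weight decay 1e-3, batch
size 1) and no early stopping; the final-epoch weights are evaluated. The
learning rate is a single constant by default, but `train_config()` also
accepts a per-epoch vector (a zero entry freezes that epoch), which the
desk-scale experiments below use to probe decay and warm-up schedules.
The epoch count is a configuration knob: the reference protocol does not
fix one.

Reports contain per-fold confusion matrices (rows true, columns predicted,
class order LGG, HGG, HEALTHY everywhere), per-class precision, recall,
specificity and F1 (one-vs-rest; zero-denominator cases report 0 with a
warning), per-class mean ± SD of F1 over folds (sample SD, n−1), and
consolidated macro F1 (unweighted mean), weighted F1 (weighted by test-set
support) and accuracy. Consolidated scores are computed on the pooled
(summed) confusion matrix; the mean of per-fold accuracies is also
reported since either convention is defensible.

The pre-trained-weight *policy* is implemented by `load_pretrained()`:
every parameter outside the stem and the fully connected head is copied
from a donor parameter set, while stem and head keep their fresh random
initialisation (a video-trained donor has a 3-channel stem and a
400-class head, so neither transfers). Acquiring such donor weights is out
of scope; the function is exercised with package-built donors.

## The phantom generator

Real cohorts (BraTS, IXI) cannot ship with a package, so `resvol` generates
skull-free phantom volumes whose class structure mirrors what the
classifier must learn from contrast-enhanced T1: an ellipsoidal "brain"
(intensity 0.5 ± textured noise) on an exactly-zero background; LGG adds
one homogeneous hyperintense ball (+0.30); HGG adds one ball whose outer
shell is hyperintense (+0.35) and whose inner half-radius core is
hypointense (0.25 below brain tissue), mimicking rim enhancement around
necrosis; HEALTHY adds nothing. Defaults are 64³ voxels at 2 mm, 60
volumes per class, lesion radii 6–10 (LGG) and 8–13 (HGG) voxels, tissue
texture SD 0.02 and noise SD 0.05. The radius defaults are clinically
grounded — 2.4–5.2 cm diameter, 1.5–5% of the volume, in line with
typical glioma/glioblastoma volumes in public segmentation cohorts — and
that size matters beyond realism: a lesion occupying well under 0.5% of
the volume sits inside the upper tail that the [0.5, 99.5] percentile
normalisation clips, so preprocessing would map diffuse tissue noise and
the lesion to the same ceiling intensity and erase the class cue. An
artefact of an undersized phantom, not of the method. Tissue and noise
draws are Gaussians truncated at 2 SD by inverse-CDF sampling (no point
mass at the bound), so intensity extremes are bounded and the class
margins hold deterministically: the brightest healthy voxel stays below
the dimmest lesion threshold by construction. Volumes and manifests are
bit-reproducible from the spec's seed.

What the phantoms deliberately do not emulate: anatomy (no cortex,
ventricles or skull), multi-contrast appearance, bias fields, partial
volume effects, scanner noise statistics, or ambiguous intermediate
grades. Passing the end-to-end test therefore shows that the pipeline —
generator, preprocessing, augmentation, networks, objective, protocol,
reporting — is wired correctly and can recover class structure that is
present in the data; it says nothing about accuracy on clinical MRI.

## Desk-scale study conditions

The published headline numbers (macro F1 0.9345, 96.98% accuracy) come
from GPU-scale training on BraTS/IXI and are not reproducible on a CPU
budget; the package's end-to-end test substitutes a property: on the
default 60-per-class phantom dataset, the full 3-repeat 70/30 protocol
with a width-reduced mixed-convolution network must reach macro F1 ≥ 0.90
and beat the majority-class baseline by ≥ 0.3 accuracy. The desk-scale
protocol is fixed once: width 4 (stage widths 4/8/16/32 — the `width`
knob scales all stages and the (2+1)D stem's 45 intermediate channels
proportionally), dropout 0, Adam learning rate 2e-3, weight decay 0,
6 epochs, augmentation on, seeds pinned. The full-width defaults
(width 64, dropout 0.3, learning rate 1e-5, weight decay 1e-3) remain
the package defaults; the reduced variant's training hyperparameters
differ for reasons that are themselves instructive. The higher learning
rate compensates for the tiny network and short schedule. Dropout 0.3 is
calibrated for a 512-feature head; on a 32-feature head it destabilises
a short schedule. And with weight decay folded into Adam's gradient,
the decay term dominates low-gradient directions under Adam's
per-coordinate normalisation, which at this scale suppresses the
late-emerging LGG-vs-HGG distinction (runs plateau around macro F1 0.83
regardless of added epochs); with weight decay 0 the same schedule
separates all three classes.

Measured outcome, stated plainly: with everything above pinned, the
protocol reaches pooled accuracy 0.8765 and pooled macro F1 0.8764 in
about ten minutes on one CPU. The accuracy, determinism and runtime
clauses of the end-to-end test pass; the macro-F1 ≥ 0.90 clause does
not, and the test asserts the design target rather than the achieved
value, so the gap is visible instead of papered over. The shortfall was
mapped rather than tuned around: fourteen training configurations —
constant rates 1e-3–3e-3, per-epoch decay and warm-up schedules, widths
3/4/6, batch size 2, dropout 0/0.1/0.3, augmentation off, residual
zero-init off, up to 13 epochs (the most that fit the 15-minute bound) —
all land between pooled macro F1 0.74 and 0.88, and in every single one
the residual errors are exclusively LGG ↔ HGG while HEALTHY is 162/162.
The cause is the deliberate class overlap in the phantoms: LGG radii
6–10 voxels against HGG 8–13, with small LGG lesions additionally
contrast-compressed by the percentile clip, so lesion size cannot
separate the overlap region and the rim/necrosis cue must be learned —
which the short CPU schedule does only partially. That this is an
optimisation-budget limit and not a wiring defect is covered by the rest
of the suite: the identical pipeline drives the loss down monotonically
and overfits a small separable phantom set to 100% training accuracy,
and the generator's class margins and clip-tail behaviour are asserted
directly.

## Numerical and engineering notes

* **Compute engine.** No deep-learning framework is assumed: forward and
  backward passes are implemented in the package, with direct
  (non-im2col) C++ convolution kernels, C++ batch-norm and ReLU, and
  plain-R Adam. Feature maps are channels-last (slice, row, col, channel)
  arrays; convolution weights are `(out, in·K)` matrices with kernel
  offsets ordered slice-fastest. The convolution kernels are verified in
  the test suite against a slow reference implementation, adjoint
  identities, and finite differences.
* **Batch-norm with batch size 1.** Normalisation uses each sample's own
  per-channel spatial statistics in *both* training and evaluation. With
  the batch-size-1 protocol, the video-network convention — running-average
  statistics at evaluation — systematically mismatches the per-sample
  statistics the optimiser saw, and on small cohorts this collapses
  held-out accuracy to chance while training accuracy is perfect (we
  observed exactly this). Per-sample statistics keep the evaluation map
  deterministic (it depends only on the input) and follow the
  instance-normalisation convention that volumetric medical-imaging
  pipelines adopted for the same reason. Running statistics are still
  tracked with momentum 0.1 and stored in checkpoints. The reference
  description does not specify evaluation-time semantics, so this choice is
  documented here as the package's convention.
* **Residual initialisation.** The final batch-norm scale of every block
  is initialised to zero (`zero_init_residual`, on by default), so blocks
  start as identities and residual branches fade in — a standard residual
  network option that stabilises short schedules. Parameter counts are
  unaffected. With it, full gradient flow to every tensor is established
  after the first optimisation step rather than at step zero.
* **Determinism.** All randomness (weight init, shuffling, augmentation,
  dropout, phantom generation, splits) derives from integer seeds in the
  configuration objects; identical seeds give bit-identical runs on the
  same platform. Evaluation-mode forward passes are deterministic.
* **Degenerate inputs.** Constant volumes are rejected by the percentile
  scaler; resampling that would collapse an axis errors; channel
  mismatches and convolution outputs that would collapse to zero extent
  error with the offending layer named (the padded reference
  architectures accept arbitrarily small inputs thanks to adaptive
  pooling); non-finite logits or losses abort training with a diagnostic.
* **Problem sizes in the tests.** Unit tests use 24³ phantoms and width
  2–4 networks; the end-to-end test uses the full default 64³ spec. These
  sizes are the package's chosen desk-scale study conditions.

## Known limitations

* Orientation metadata in NIfTI headers is not interpreted: axes are used
  in stored order. Datasets mixing orientations must be harmonised
  upstream.
* The engine is CPU-only and double-precision; it is built for
  correctness and desk-scale sizes, not for training full-width networks
  on real cohorts.
* `load_pretrained()` implements the transfer policy, not weight
  acquisition; no pre-trained donor is bundled.
* The batch-norm train/eval mismatch at batch size 1 (above) can depress
  evaluation scores on very small training sets; it fades with training-set
  size and is part of the faithful protocol rather than a defect of this
  implementation.
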