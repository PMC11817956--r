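---
title: "Small-lesion segmentation feasibility: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-lesion segmentation feasibility: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroseg)
```

## The scientific problem

Metastatic brain lesions are often small — by the working definition used
here, a *small* tumor is one whose largest per-slice area across all axial
slices is below 3.5 cm² (slightly above the area of a 2 cm circle).  Small
lesions are exactly the ones worth catching early, yet they are nearly
absent from public training resources: large challenge datasets contain
primary tumors that are typically conspicuous, and a mid-size hospital can
realistically label only a few dozen in-house cases.  `neuroseg` implements,
as a reusable and fully tested pipeline, the study design for asking whether
anything useful can be trained under those constraints: DICOM-style
preprocessing to a canonical tensor, two 3D segmentation architectures,
geometric augmentation, cutout-based contrastive self-supervised
pretraining, transfer protocols with layer freezing, cross-validation
orchestration, and Dice/detection scoring — all exercisable end to end on a
bundled synthetic phantom generator, with no downloads and no GPU.

## The canonical tensor and the preprocessing chain

Every model consumes a paired image/label volume of exactly 128×128×64
voxels (network strides require dimensions divisible by 32).  Two input
routes produce it.

**Clinical-style series.**  Stored 12-bit pixel values pass through the
DICOM grayscale chain:

1. *Modality LUT* — the affine rescale `v = m·v_org + b0` with the
   slope/intercept attributes, mapping stored values to physical units.
2. *VOI LUT* — the windowed contrast map: 0 below `c − w/2`, the display
   maximum `g_m` above `c + w/2`, and linear with slope `g_m/w` inside.
   We implement this simplified linear dialect exactly as stated rather
   than the DICOM standard's `(w−1)/(c−0.5)` variant, because the study's
   conversion is self-consistent and reproducible.  Values exactly at the
   window edges take the linear branch; the function is continuous.
3. *Presentation LUT* — per-case min–max normalization to integers in
   [0, 4095]; a constant case maps to zero.  "Normalize to 12-bit" admits
   several readings; min–max is the simplest monotone one and the whole
   raw→12-bit composite is covered by a monotonicity property test.

Polygon annotations (closed polylines keyed by slice instance UID) are
rasterized with an even-odd fill plus a boundary stroke of the stated
segment width (minimum one pixel) — "fill the inside of the closed lines"
plus the drawn lines themselves.  Thin stacks of 24–25 slices are
interpolated along the slice axis so that originals are reproduced exactly
at even indices and midpoints are synthesized by Keys cubic convolution
(the pluggable stand-in for the cited high-order slice interpolation;
linear is selectable).  The 2S−1 arithmetic gives 47 slices for S = 24 but
49 for S = 25, which conflicts with the documented 47–48 range; we
reconcile by dropping the final interpolated slice for S = 25.  Stacks are
then zero-padded at the end to 64 slices and finally resampled in-plane to
128×128 (bilinear for images, nearest for labels).  The size class is
always computed *before* resampling, at native pixel spacing, as
foreground pixel count × spacing²; this makes the class invariant to the
resampling that follows.

**Challenge-style volumes.**  240×240×155 labeled volumes are decimated
with `u_i = s_{16+2i}`: starting at 0-based slice 16 — the first 15 slices
are blank — every other slice is taken until 64 remain (input indices
16..142).  Labels {1, 2, 4} (necrotic core, edema, enhancing tumor) are
merged to a single foreground label, and the volume is resampled in-plane
like the clinical route.

## The two architectures

Both networks are written from first principles in this package (compiled
im2col convolutions with BLAS matrix products; hand-derived backward passes
verified against finite differences), because no deep-learning framework is
part of the supported R stack.  The contracts are structural and scale with
a single knob, so desk-scale variants preserve every shape relation of the
full-scale configuration.

**Residual U-net.**  A stride-1 stem convolution lifts the input to
`base_channels` (default 16), then four residual encoder blocks
(stride-2 conv → instance norm → ReLU → stride-1 conv → instance norm →
ReLU, with a projection bypass) each double the channels and halve every
spatial dimension; counting the stem this is five encoder blocks, and at
the defaults the bottleneck activation is 256×8×8×4.  Four decoder blocks
mirror the ladder with stride-2 transposed convolutions, skip
concatenations and residual convolutions, and a final 1×1×1 convolution
reduces to two channels.  The predicted mask is the channel argmax, with
ties going to background — a deliberate choice that makes `segment()`
deterministic and favors specificity.

**Swin-style transformer.**  A stride-2 patch embedding to `embed_dim`
(default 48) is followed by four patch-merging stages, each doubling
channels and halving resolution, so the channel ladder ends at
`16 × embed_dim = 768` with a 4×4×2 bottleneck at full scale.  Every stage
carries a W-MSA/SW-MSA attention pair (layer norm → windowed multi-head
self-attention → layer norm → MLP, with residual connections).  The shifted
variant cyclically rolls the volume by half a window; we do not mask
attention across the wrapped boundary — a simplification that preserves all
shape and training contracts and keeps the backward pass tractable.  The
decoder has five blocks of {transposed convolution; concatenation with the
encoder feature passed through a residual convolution sub-block; residual
sub-block}, ending at a 48-channel full-resolution feature and a 1×1×1
head.  Attention windows default to 4 voxels per axis, clipped to the stage
resolution (the deepest stage attends in 4×4×2 windows); incompatible
windows are rejected rather than silently padded.

"Bottom two layers" in the layer-freezing transfer protocol is interpreted
as the two decoder blocks nearest the output plus the final head — the
natural reading of freezing everything except where small-lesion
specialization must happen.  Parameter groups ({encoder, decoder,
bottom_two, head}) partition all weights, and the freeze contracts are
asserted by bit-identity of frozen groups after optimization steps.

## Self-supervised pretext task

Two corrupted views of each unlabeled volume are built by replacing
rectangles with uniform noise over the volume's intensity range: the inner
view cuts 6 crops of 5–32 px from the central half of the slice extent, the
outer view 6 crops of 20–64 px intersecting the border band (the outer
quarter).  Crop sizes are stated for the canonical 128² plane and shrink
proportionally for smaller volumes.  Because the quoted sizes are 2D for 3D
data, each rectangle is replicated across a random contiguous slab of
slices, keeping the corruption three-dimensional.

Both views pass through the transformer encoder.  The contrastive term is a
normalized-temperature softmax cross-entropy over in-batch negatives
(temperature 0.5) computed on spatially pooled bottleneck features passed
through a two-layer projection head: the description ties the loss to the
reconstructions, but the cited contrastive framework operates on
embeddings, and embedding space is the defensible default (at the
identical-embedding point the loss equals ln(2N−1), which the tests pin for
N ∈ {2, 4, 8}).  The outer view is additionally decoded by a light
transposed-convolution head and compared to the *uncorrupted* volume with
an L1 penalty.  The combined loss is `contrastive + λ·L1` with λ = 1
(config-exposed).  Downstream, the pretrained encoder is transplanted into
the full segmentation network and frozen; only the decoding path trains.

## Augmentation

Four in-plane transforms, applied slice-wise with one parameter draw per
case: rotation by ±20–50°, scaling by 0.6–0.9 or 1.1–1.5 (the sampler can
never produce a near-identity scale), both combined, and a fixed 0.4 shear.
Sign and branch are fair coins; magnitudes are uniform.  An augmentation
rate of N means the training list grows to N× its size — each original plus
N−1 transformed copies cycling over the four kinds.  Evaluation data are
never augmented, and augmented variants inherit their source id so
cross-validation keeps them on the training side with their source.

## Training and evaluation

The segmentation loss is a soft-Dice over the two-channel softmax (the
observed training-loss scale of a Dice-type loss matches the study's
narrative; cross-entropy is selectable).  The optimizer is Adam at learning
rate 1e-3 — unstated in the source material, so chosen as the field
default and config-exposed.  One master seed derives every stage seed, and
full runs are bit-deterministic.  At leave-one-out scale there is no spare
validation data for checkpoint selection, so final-epoch weights are used;
the runner supports threefold and leave-one-out fold plans, train-set
unions, and a detection mode in which tumor-free cases are never part of
any training fold and are scored once by a model trained on all tumor
cases.

Dice is `2TP/(2TP+FP+FN)` on voxel counts.  When prediction and truth are
both empty the score is defined as 1: a correct all-negative segmentation
should not be penalized, and tumor-free cases are scored by detection, not
Dice.  Case-level detection is "some 26-connected component with at least
`min_component_voxels` voxels" (default 1 — any predicted voxel counts; the
threshold is exposed because the original criterion is unstated).
Sensitivity, specificity and the hyperintensity-excluded specificity are
reported as percentages rounded half-up to one decimal.  The
`dice_offset_study()` helper reproduces the size-bias analysis: under a
fixed one-pixel offset the Dice of an s×s square is
`2(s−1)²/(2(s−1)² + 2(2s−1))`, strictly increasing in s — the analytic
reason small-lesion Dice is systematically low even for visually good
segmentations.

## The phantom generator

The generator is the package's test bed and defines the study conditions it
emulates: a cohort of 18 large-tumor, 15 small-tumor and 22 normal cases
(7 of them carrying bright white-matter-hyperintensity-like speckles),
47–51 axial slices per case with a minority of thin 24–25-slice stacks,
12-bit stored pixels behind rescale slope/intercept and window
center/width metadata, and polygon annotations exactly on slices with
lesion foreground.

Lesions are axis-aligned ellipsoids with a smooth intensity falloff, so the
per-slice area is analytic (πab at the equator) and the 3.5 cm² class can
be enforced by construction; small-lesion target areas are log-normal with
median 1.1 cm², truncated with enough headroom below 3.5 cm² that the
annotation boundary stroke cannot flip the class after rasterization.
Large-lesion areas are uniform on 4.5–12 cm².  The background is an
ellipsoidal "brain" with low-frequency multiplicative plane-wave texture
plus Gaussian noise — enough structure that plain thresholding does not
solve the task, which keeps the scaled-down training experiments
meaningful.  Pixel spacing defaults to 0.9 mm, a realistic head-MRI value
(unstated in the source data) that puts a 1.1 cm² lesion at roughly 13
pixels across a 256² matrix and ~7 after resampling to 128² — the
few-pixel regime that drives the Dice size bias.  Hyperintensity speckles
are small bright blobs (< 0.3 cm² per slice) added only to tumor-free
cases and never entering the truth mask.

What the phantoms deliberately do **not** emulate: MRI physics (bias
fields, multi-coil inhomogeneity, modality-specific contrast), skull
stripping, real anatomy, or annotation disagreement between raters.
Passing tests on phantoms therefore demonstrates that the pipeline's
mechanics — format handling, geometry, losses, freezing, bookkeeping — are
correct and that the networks can learn separable synthetic lesions; they
say nothing about clinical segmentation accuracy, for which the real data
and full-scale GPU training remain necessary.

## Numerical choices and problem sizes

All backward passes are hand-derived and verified against central finite
differences at tolerance 1e-6–1e-5 relative.  Instance/layer norm use
ε = 1e-5; the soft-Dice loss is smoothed with ε = 1.  Weight
initialization is He-style for convolutions and small-variance normal
(σ = 0.02) for transformer weights.  The test and example experiments run
at desk scale by design — 32³–64×64×32 volumes, 4-channel U-nets,
6-channel transformer embeddings, cohorts of tens of cases — sizes chosen
so the whole suite, including two cross-validated training comparisons and
a learnability run, completes on a single CPU while exercising every
structural contract of the full-scale configuration (whose 128×128×64
forward passes are also run once, taking ~30 s for the U-net and ~2–3 min
for the transformer).  The full-scale *training* experiments of the
original study (hundreds of labeled volumes, 100-epoch budgets, GPU) are
out of scope; the runner documents the configuration for users who have
the data.

## Known limitations

* The shifted-window attention omits boundary masks after the cyclic roll.
* The contrastive default operates on pooled embeddings; image-space
  similarity on reconstructions is possible in principle but not the
  default.
* The connected-component detection rule is a stand-in for an unstated
  clinical criterion; its threshold is exposed and defaults to a single
  voxel.
* Phantom realism is intentionally limited (see above); absolute Dice
  values obtained on phantoms are not comparable to clinical values.
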