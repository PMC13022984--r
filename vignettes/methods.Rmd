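---
title: "Frequency- and texture-enhanced lesion segmentation with dual-teacher distillation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lesion segmentation in H&E-stained colorectal sections is hard for three
reasons: lesions span an order of magnitude in size across pathological
grades; contrast between dysplastic and healthy epithelium is often low and
boundaries are ambiguous; and pixel-annotated datasets are small. `histoseg`
implements a segmentation network that attacks each of these with a
dedicated mechanism — a multi-scale dilated-convolution pyramid with dual
attention and edge refinement (MS-ASPP), a frequency/texture enhancement
block (AFE-TAM), and a progressive dual-teacher knowledge-distillation
training protocol (PDTKD) whose teachers exist only at training time, so
inference runs on the lightweight CNN student alone.

## The computational substrate

No deep-learning framework is part of the package's dependency set. All
trainable blocks run on a small reverse-mode automatic-differentiation
engine on plain R arrays (`R/autodiff.R`): tensors are environments holding
a value, an accumulated gradient and a backward closure; graphs are rebuilt
per forward pass; convolutions use cached-index im2col and BLAS matrix
products. The engine is sized for desk-scale networks (tens of layers,
images up to a few hundred pixels) and is validated by finite-difference
gradient checks at float64 (relative error below 1e-3 is required by the
test suite for the complete MS-ASPP block; typical values are ~1e-8).
Adam is the optimizer throughout.

Feature maps are `(row, col, channel, sample)` arrays. The H×W×C ordering
seen in network diagrams is notational; this layout keeps R's column-major
indexing efficient.

## MS-ASPP (inserted at 1/8 resolution, 2C channels)

Five parallel branches, each emitting C/4 channels: a 1×1 convolution, a
3×3 convolution, two 3×3 dilated convolutions with rates 6 and 12
(effective receptive fields `k + (k-1)(r-1)` = 13 and 25), and a
global-average-pool context branch (pool → 1×1 conv → broadcast). The
literature around this architecture sometimes quotes a third dilation rate
of 18; the block as specified by its equations has exactly five branches,
and `aspp_config(dilation_rates = c(6, 12, 18))` enables the six-branch
variant if wanted. Channel attention (GAP → bottleneck `5C/4 → max(1,
floor(5C/32)) → 5C/4` → sigmoid) and spatial attention (per-pixel channel
max/mean → 7×7 conv → sigmoid) are applied as a single elementwise product.
A learnable edge branch starts from a classical operator: depthwise 3×3
kernels initialized to a Laplacian difference stencil (+1 center, −1/8
ring) under reflection padding, so a constant input produces an exactly
zero edge response before any training; a pointwise convolution lifts it
to 5C/4 channels and a 3×3 convolution follows. Fusion is
`F_attn + λ·F_edge` with a single scalar λ initialized to 0.3 and left
unconstrained, then a 1×1 projection back to C channels.

Design points that were genuinely open and the choices made:

* Batch normalization follows every branch convolution (the block
  description is silent; this matches common ASPP practice and stabilizes
  the small-batch training used here).
* The edge branch emits 5C/4 channels so the fusion is a plain elementwise
  sum — the minimal reading that type-checks.
* Detector order is stencil → pointwise → 3×3 conv.

## AFE-TAM (inserted at 1/16 resolution, 4C channels)

**Spectral path.** Each channel is Fourier-transformed, center-shifted, and
split into three bands by distance from the center bin at radii
`0.15·sqrt(H²+W²)` and `0.45·sqrt(H²+W²)` (half-open intervals, so the
three masks partition the grid exactly). Note a geometric consequence of
the literal radii: on a square grid the outer radius 0.45·√2·H exceeds the
axis-aligned Nyquist distance H/2, so the "high" band contains only
near-diagonal frequencies; an axis-aligned period-2 cosine falls in the
mid band. The implementation follows the literal formula and the tests
document this behavior. Each band is scaled by `sigmoid(θ_b) · α_mode[b]`,
the product of a learnable weight (θ initialized to 0, i.e. a neutral 0.5)
and the category-adaptive preset mix; a convex combination
`(w_b + α_mode[b])/2` is available behind `afetam_new(combine =
"convex")`. The inverse transform's real part returns to the spatial
domain. With all effective multipliers equal to 1 the path is the identity
up to float error, and the operator is self-adjoint, which the engine
exploits: the backward pass is the same band filter applied to the
gradient.

**Texture path.** A 1×1 projection to a single channel feeds (a) a fixed
Gabor bank — 8 orientations × 4 wavelengths (2, 4, 8, 16 px), ψ = 0,
γ = 0.5, σ = 0.56λ (≈ one octave), kernel size `2·ceil(2.5σ)+1` capped at
31 — whose 32 responses are compressed to 8 channels (with ψ = 0 the θ and
θ+180° kernels coincide; the redundancy is documented, not removed); and
(b) a learnable local-binary-pattern layer: eight 3×3 signed
neighbor-difference stencils, a steep sigmoid (slope 10) as the
differentiable sign, and binary-weight pooling Σ s_p 2^p scaled by 1/255
so the channel is O(1). At initialization the layer reproduces hard LBP
codes on patches whose neighbor gaps exceed the sigmoid's soft zone;
`lbp_reference()` is the oracle. Texture attention standardizes the 5×5
local variance of the channel-mean map (ε = 1e-5) and applies a 3×3 conv
and sigmoid; the per-sample normalization statistics are treated as
constants in the backward pass (an instance-norm-style approximation that
keeps the graph simple — parameter gradients remain exact, input gradients
through the statistics are truncated). The variance window uses reflection
padding: the 1/16 insertion point of a 64-px desk-scale input is a 4×4
map, where a "valid" 5×5 window would not exist.

**Category adaptation and fusion.** A light detector (GAP → 16-unit MLP →
softmax over the six colorectal categories) mixes per-category preset band
weights (`Normal = [0.3, 0.3, 0.4]` emphasizing high frequency, `Low-grade
IN = [0.4, 0.4, 0.2]`, the remaining four uniform and configurable). The
detector is trained implicitly through the segmentation loss; no category
labels are consumed at run time, and `afetam_forward_detail()` exposes the
probabilities for an optional auxiliary loss. Output is the residual
fusion `F + α_freq·F_freq + β_texture·F_texture` with both scalars
initialized to 0.5.

## Backbone and teachers

The student is a stride-4 stem (two stride-2 3×3 convs), three residual
stages (two blocks each) at C, 2C, 4C, MS-ASPP after the 1/8 stage,
AFE-TAM after the 1/16 stage, and a decoder of progressive 2× bilinear
upsampling with additive skip fusion; class logits are produced at 1/4
resolution and bilinearly upsampled. Taps at 1/4, 1/8, 1/16 are
retrievable by name. Input images in [0,1] are centered by −0.5 at the
network boundary.

Teacher 1 is a transformer branch: convolutional patch embedding to 1/8,
transformer layers there, patch merging to 1/16 and further layers whose
last-layer attention (averaged over heads) is the supervision surface — a
row-stochastic N×N map over the 1/16 token grid, matching the student's
`student_attention()` geometry. Teacher 2 is a residual-encoder U-shaped
network; its encoder can be seeded from generic-image pretrained weights
when a checkpoint is available, and otherwise keeps its random
initialization with an explicit log message, so desk-scale runs are fully
offline. At desk scale the teachers are deliberately shallow (one
transformer layer per resolution, two residual blocks per stage); at the
default 256-px/64-channel configuration the student has fewer parameters
than the two teachers combined, which the tests assert.

## The training protocol

Losses (per teacher): temperature-softened KL on logits (T = 4, scaled by
T², printed argument order KL(student‖teacher); `kl_direction = "reverse"`
is available), feature MSE at 1/4, 1/8, 1/16 through trainable 1×1
aligners (mean-reduced per scale in training; a sum-reduced mode exists
for oracle tests), attention Frobenius matching (teacher 1 only, weight
δ = 0.2), and batch cosine-relation matching (weight η = 0.1); the feature
weight is γ = 0.3 and the combined teacher losses enter with dynamic
weights α (init 0.5) and β (init 0.3). The segmentation loss is Dice
(smoothing 1) plus α-balanced focal loss (γ = 2, α = 0.25), equally
weighted.

Stages split the epoch budget 40/40/20 (`ceil(0.4E)`, `ceil(0.8E)`) with
learning rates 2e-4 / 1e-4 / 5e-5 for the student. Stage 2 re-evaluates
teachers on the validation split every K = 5 epochs and applies the
asymmetric update (+0.1/−0.05 toward the better teacher, clamped to [0,1],
no normalization — α+β may drift, as printed); the curriculum fraction
grows linearly from 20% to 50% of training samples flagged hard (top
difficulty = 1/Dice, united with the absolute rule Dice < 0.7 or
HD95 > 20 px, both strict; the HD95 threshold is defined at 256-px
resolution and scaled proportionally at other sizes). Hard samples receive
weight 2.0 on their segmentation term. Stage 3 draws teacher dropout with
p = 0.5 per step from a named seeded stream — a dropped step trains on the
segmentation loss alone, an undropped step adds KD restricted to hard
samples. Augmentation consistency (inverse-mapped predictions of flipped /
±15°-rotated / brightness-shifted views; rotations invert by
nearest-neighbor warp, flips exactly) is added with weight 0.1 in stages
2–3. Early stopping uses validation-loss patience (default 20) and the
returned student carries the best-validation weights.

Interpretations recorded as the package's own choices:

* "Student performance after teacher guidance" for the dynamic weights is
  operationalized as each teacher's own validation Dice.
* Both teachers are task-adapted by a short segmentation-only warm-up (5
  desk-scale epochs on their own optimizers at 1e-3) before distillation
  begins, so their targets are informative from the first distilled step.
  Teacher 2 is then frozen; teacher 1 continues to train jointly with the
  student through stage 1 (dual-branch training) and is frozen afterwards
  as the protocol shifts to student autonomy. The staged learning rates
  govern the student; auxiliary-branch optimizers keep a constant 1e-3.
* Training epochs iterate an augmentation-expanded set: each epoch visits
  every clean sample plus `aug_expand − 1` freshly augmented views
  (default 3), an offline-style expansion of the small training set. The
  consistency view is computed on alternating steps.
* One named seeded stream each exists for initialization, augmentation,
  batch order and dropout draws; the manifest records them, so runs are
  bit-reproducible on one device.

## Synthetic study conditions

The generator (`generate_synthetic()`) emulates the six-category structure
of colorectal section data: seeded colored-noise backgrounds over an
H&E-like tint with a category-specific dominant frequency band, and
lesions as random harmonic-modulated blobs whose count, scale, boundary
style and contrast differ per category. Serrated-adenoma-like lesions
carry a 9-lobed scalloped outline; adenocarcinoma-like lesions use strong
low-order shape modulation; Normal-like images are 70% lesion-free and
otherwise contain one faint blob at contrast 0.05. The low-contrast
category is Low-grade-IN-like (contrast 0.10 against noise sd 0.07) —
chosen so a trivial Otsu baseline reaches Dice ≥ 0.6 on the
high-contrast categories (Polyp-, Serrated-like, contrast 0.45) but below
0.4 there, which the tests assert: the benchmark is neither trivial nor
impossible. Lesion interiors also carry a shifted texture band, giving
models a texture cue beyond raw intensity, as real lesions do.

What the generator does not emulate: stain variability, glandular
micro-architecture, imaging artifacts, annotation noise, or inter-center
shift. Passing the desk-scale tests therefore demonstrates that the
training machinery optimizes what it should and that the blocks behave as
designed — not that the published accuracy transfers to real
histopathology data.

The desk-scale problem sizes used throughout the tests and the acceptance
script are 64×64 images, 10 samples per category (60 total, split 8:1:1
per category), a 16-channel student, 10 epochs with batch size 2 and
expansion 3, and 3 seeds for stochastic checks; these sizes keep a full
protocol run in the minutes range on one CPU while exercising every stage
transition.

## Numerical choices and degenerate inputs

FFT-shift centers at index `floor(n/2)` (0-based) for even and odd sizes,
matching the standard convention so the band-identity property holds
bit-for-bit. Half-open band intervals guarantee the partition. Empty-mask
conventions: both masks empty → overlap metrics 1 and surface distances 0;
exactly one empty → overlap 0 and both surface distances equal the image
diagonal (a bounded, monotone penalty). Boundaries use 4-connectivity;
mIoU is the image-level two-class mean IoU macro-averaged over images, and
every report states this definition. `predict_masks()` removes predicted
connected components below 0.5% of the image area (standard small-object
suppression; `min_size = 0` disables it). The batch-relation loss is 0
with a warning for batches of one. Division guards use ε = 1e-5 (texture
standardization), 1e-8 (Adam), 1e-12 (logs).

## Known limitations

The engine is single-threaded R; it is meant for desk-scale study of the
training dynamics, not for full-resolution training. The exact internals
of the upstream real-time backbone family are not public, so parameter and
FLOP parity with published totals is out of scope; the package instead
ships the published benchmark tables (`benchmark_tables()`) and recomputes
their aggregate arithmetic (`benchmark_summary()`). Under the desk-scale
epoch budget the prescribed staged learning rates bound how far Adam can
move the weights, and results are correspondingly sensitive to the
expansion factor and batch size documented above.
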