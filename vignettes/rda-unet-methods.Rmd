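---
title: "Kidney CT segmentation with a residual dual-attention U-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney CT segmentation with a residual dual-attention U-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdaunet)
```

## Problem

Renal cysts are common, benign structural changes of the kidney whose
size and number matter for the management of chronic kidney disease.
Quantitative follow-up needs two ingredients from abdominal CT: accurate
per-slice segmentation of the kidneys (cysts included), and the total
kidney volume (TKV) obtained by stacking those per-slice masks into a
3-D reconstruction. `rdaunet` implements this pipeline end to end: a
segmentation network, Dice-loss training, left/right evaluation metrics
split at the spine, and voxel-counting volumetry — plus a synthetic
phantom generator that stands in for clinical data, which is rarely
shareable.

## The network

The model is a U-shaped fully convolutional network whose feature blocks
are *residual dual-attention* (RDA) blocks. One block computes, for
input $X$:

1. two zero-padded $3\times3$ convolutions (each followed by batch
   normalization and ReLU), giving features $Y \in \mathbb{R}^{w \times w \times c}$;
2. a **spatial attention mask** $Q(Y) \in (0,1)^{w \times w \times 1}$:
   a $1\times1$ convolution across channels followed by a sigmoid, one
   gate per position;
3. a **channel attention code** $P(Y) \in (0,1)^{1 \times 1 \times c}$:
   global average pooling over positions, a $1\times1$ convolution
   across channels, and a sigmoid, one gate per channel;
4. the gated sum $Y' = Q(Y) \otimes Y + P(Y) \otimes Y$, with $Q$
   broadcast over channels and $P$ over positions ($\otimes$ is
   element-wise multiplication);
5. an identity residual: $\mathrm{ReLU}(Y' + X)$, where $X$ passes
   through a learned $1\times1$ projection only when the channel counts
   differ.

The full network is encoder–bottleneck–decoder–classifier: `depth`
encoder stages (RDA block + $2\times2$ max pooling, channel width
doubling from `base_channels`), a bottleneck of two $3\times3$
convolution layers, a mirrored decoder ($2\times2$ transposed-convolution
upsampling, concatenation skip connection to the same-level encoder
output, RDA block), and a $1\times1$ convolution to 2 classes with a
per-pixel softmax. Plain U-Net baselines (with and without batch
normalization) share the topology with the RDA block replaced by a
double convolution.

Two points in this design were genuinely open and resolved here:

* The channel code $P$ must reduce the spatial dimensions to $1\times1$;
  no reduction operator is prescribed, so global average pooling (the
  standard squeeze operation) is used before the $1\times1$ convolution.
* Whether the attention sum *replaces* or *precedes* the residual
  addition is ambiguous in prose descriptions of such blocks; this
  implementation computes attention-sum, then identity residual, then
  ReLU. Kernel sizes of the non-attention convolutions (never stated)
  are $3\times3$; upsampling uses $2\times2$ stride-2 transposed
  convolutions; skip fusion is channel concatenation.

No deep-learning framework exists in the supported environment, so all
forward **and** backward passes (convolution via im2col/GEMM, batch
normalization, pooling, transposed convolution, the attention gates, the
softmax/Dice gradient and Adam) are implemented in the package itself
(RcppArmadillo for the convolution kernels). Correctness of every
gradient path is established by finite-difference tests and the
attention gate by a scalar brute-force oracle.

## Loss and optimization

Training minimizes the soft Dice loss over the foreground (kidney)
class,

$$\mathcal{L} = 1 - \frac{2\sum_y h(y)\,k(y) + \varepsilon}
{\sum_y h(y)^2 + \sum_y k(y)^2 + \varepsilon},$$

with $h$ the predicted foreground probability, $k$ the binary reference,
and $\varepsilon = 10^{-6}$ a smoothing constant that makes the
empty-mask case well defined (the reference protocol is silent there).
The loss is evaluated on the foreground class only — the formula is
written for a single category, and the background probability is implied
by the softmax; a per-class average would be a trivial extension and is
deliberately not the default.

The optimization protocol follows the reference settings: mini-batches
of 16, Adam with $\beta_1 = 0.95$ (the stated "momentum" — Adam has no
classical momentum, so it is read as the first-moment decay; $\beta_2$
stays at the conventional 0.999), classical L2 weight decay $10^{-4}$
coupled into the update (applied to weight tensors, not biases or batch
normalization parameters), learning rate $10^{-3}$ dropping to $10^{-4}$
once 30 epochs are completed (epoch 30 itself still uses $10^{-3}$), 50
epochs, and checkpoint selection by the smallest mean loss — training
loss by default, or held-out loss when a validation fraction is
requested.

## Preprocessing

CT inputs are converted to Hounsfield units via the DICOM rescale
slope/intercept and windowed with width 420 HU, center 60 HU: values are
clipped to $[-150, 270]$ and mapped linearly to $[0,1]$. This window
mapping *is* the normalization — no per-image statistics are used, since
the protocol says only that images are normalized and per-window scaling
is the standard radiology reading. "Window position" is read as window
center/level. Images are resampled bilinearly (masks nearest-neighbor,
so they remain binary) to $256\times256$, and the training set is
doubled by deterministic horizontal flipping (originals first, then
mirrors) rather than by per-batch random augmentation.

Coordinate convention: arrays are row-major displays with row 1 at the
top; under radiological display the patient's anatomical left appears on
the image right, so the "left kidney" occupies image columns at or right
of the spine column. A neurological-convention switch exists.

## Evaluation

With $E$ the predicted mask and $F$ the reference,
$\mathrm{DSC} = 2|E \cap F| / (|E| + |F|)$,
$\mathrm{precision} = SQ/(SQ+HQ)$ and $\mathrm{recall} = SQ/(SQ+HM)$,
where $SQ$, $HQ$, $HM$ count correctly predicted kidney pixels,
background predicted as kidney, and kidney predicted as background.
Scores are reported per anatomical side using the spine as the dividing
line; because no spine-localization algorithm is prescribed, the default
dividing column is the image midline, with an override flag, and on
phantoms the generator's known spine column. Empty-denominator cases are
defined as 1 (a model that correctly predicts nothing on an empty side
is not penalized). Slice scores are aggregated by pooling pixel counts
(micro-average) by default; the averaging scheme behind published
per-model tables is typically unstated, so a per-slice macro-average is
also computed and exposed.

## Volumetry

Per-slice masks are stacked into a labeled volume (0 background, 1
anatomical-left, 2 anatomical-right) and TKV is estimated by voxel
counting: $V = N_{\mathrm{vox}} \cdot s^2 \cdot d$ with in-plane spacing
$s$ and inter-slice distance $d$. CT protocols often report both a slice
thickness (1.0 mm) and a smaller inter-slice distance (~0.5 mm,
overlapping reconstruction); volume integration follows the *sampling
distance* $d$, not the thickness, because summing overlapping slabs at
their sampling step is the correct Riemann sum. Totals are exactly
left + right. Volumes export as uncompressed NIfTI-1 with the voxel
spacing in the header, so standard viewers render the reconstruction at
physical scale.

## The phantom world

The generator emulates the stated acquisition geometry: square slices
(512 or 256 px in production, smaller in tests), pixel spacing 0.625 mm,
slice thickness 1.0 mm, inter-slice distance 0.5 mm. A slice contains a
soft-tissue body ellipse (40 HU) on air (-1000 HU), a bright spine
ellipse (700 HU) on the vertical midline, and two kidney ellipsoids
(30 HU, semiaxes $a,b,c$ = 20, 15, 30 mm by default) placed
symmetrically at ±28 % of the image width with a small seeded jitter —
a placement that guarantees the spine dividing line is exactly correct,
so the left/right split can be tested against exact side labels.
Optional cysts are low-attenuation balls (10 HU) fully inside the
kidneys (sampled within the inscribed sphere); cysts count as kidney in
the binary mask, since the clinical task segments kidney contours with
their cysts. I.i.d. Gaussian noise is added everywhere; the default
standard deviation of 12 HU was chosen once as typical abdominal CT
quantum noise (neither the protocol nor the task statement fixes it) and
is deliberately of the same order as the 10 HU kidney/soft-tissue
contrast, so segmentation requires spatial context rather than
thresholding.

What a green test on phantoms does establish: the network, loss,
optimizer, metrics and volumetry are internally correct, can fit and
generalize across seeded noise, and recover analytically known volumes
within discretization error. What it does not establish: performance on
real anatomy — phantoms have no texture, no neighboring organs, no
partial-volume effects, no scanner artifacts, and far simpler shape
variability. Published clinical accuracy figures (DSC around 94–96 %)
come from a private 79-patient dataset after GPU training and are not
reproducible here; no test in this package claims them.

## Numerical choices and scale-downs

* He-normal weight initialization, seeded; batch normalization uses
  batch statistics in training, running averages (momentum 0.1,
  $\epsilon = 10^{-5}$) at inference.
* The Dice gradient folds the 2-class softmax Jacobian analytically.
* CPU test scale: training tests use 64×64 phantoms at 2.5 mm spacing
  and depth-3, 8-channel networks (~128 k parameters); the default
  production configuration is depth 4, 32 base channels (~8.2 M
  parameters), exercised forward at 256×256 in the test suite. The
  generalization test keeps the full 50-epoch schedule on 50 training
  slices; with both architectures near their performance ceiling on
  this easy geometry, the RDA-vs-baseline ordering is close and is
  asserted only in the stochastic ≥2-of-3-seeds form.
* Determinism: every stochastic step (phantom sampling, initialization,
  shuffling) derives from explicit seeds through R's RNG, restored after
  use; repeated runs on one machine are bit-identical.

## Known limitations

Single-frame DICOM (explicit-VR little-endian) and uncompressed NIfTI-1
only — the environment provides no medical-image IO library, so the
package carries minimal readers/writers for exactly the fields it needs.
PNG export of phantoms is an 8-bit windowed preview (the available PNG
writer does not produce 16-bit), with NIfTI as the HU-faithful format.
No multi-organ classes, no surface-distance metrics, no mesh export, no
GPU path.
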