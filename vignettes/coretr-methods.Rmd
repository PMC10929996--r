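---
title: "Methods: hybrid CNN/deformable-transformer segmentation of lung tumors"
author: "coretr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid CNN/deformable-transformer segmentation of lung tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Delineating the gross tumor volume (GTV) of non-small-cell lung cancer on
planning CT is the rate-limiting manual step of radiotherapy workflows such
as stereotactic ablative radiotherapy and adaptive replanning. The
segmentation task is hard for convolutional networks in a specific way:
lung GTVs span four orders of magnitude in volume (sub-0.1 cc nodules to
several hundred cc of bulky disease), and the purely local receptive field
of convolutions handles the large-context cues (mediastinal anatomy,
lesion-to-lesion relationships in multifocal disease) poorly.

`coretr` implements Co-ReTr, a hybrid architecture that addresses both ends
of that scale problem: a *dual-resolution* convolutional encoder captures
fine detail and semantics simultaneously, and a *deformable transformer*
models long-range spatial dependency at linear (not quadratic) cost in the
number of feature positions.

# The model

## Encoder: two backbones at two resolutions

The input patch (normalized CT, default $96^3$ voxels) is prepared in two
versions: upsampled by a factor of 2 (trilinear) for a **shallow** backbone
that preserves positional detail, and downsampled by 2 (average pooling)
for a **deep** backbone that extracts semantics. Each backbone starts with
a five-layer Conv--IN--ReLU stem (kernels 3, 1, 3, 1, 3; instance
normalization because batch size is 1) and continues with residual stages
built on $5^3$ convolutions: 6 stages for the shallow branch (one
downsampling between consecutive stages, strides 1 through 32), and 9
residual blocks for the deep branch, grouped 2-2-2-1-1-1 over six scales so
the two pyramids align scale-for-scale. A residual block is
$y = \mathrm{IN}(W_1 * \mathrm{ReLU}(\mathrm{IN}(W_5 * x))) + Px$ with a
$1^3$ projection $P$ only where the width or resolution changes; there is
no post-activation, so zeroing the transform weights leaves the shortcut
*exactly* — the property that makes gradient flow through deep stacks
verifiable rather than aspirational, and one the test suite asserts
literally.

Channel widths double per stage from `base_channels` (default 32, capped at
320). Where the halving ladder would shrink an axis below 4 voxels the deep
branch stops downsampling and later groups refine at the coarsest reached
scale; their pyramid contributions are summed.

## Multi-scale feature pyramid (Ms-FPN)

Both backbones' stage outputs are fused to a common width `fpn_channels`
(default $3\times$`base_channels`, a multiple of 6 for the positional
encoding below) by

$$F'_{i,j} = \mathrm{Conv}_{1^3}(F_{i,j}) + \mathrm{Up}(F'_{i,j-1})
          + \mathrm{Up}(F'_{i+1,j}),$$

where $i$ indexes the backbone (shallow above deep), $j$ the scale,
$\mathrm{Up}$ doubles resolution trilinearly, and out-of-range terms are
omitted. Propagation runs deep-to-shallow and coarse-to-fine, so semantic
content flows down-level and up-resolution. A configuration flag
(`fpn_upsample_gain = 2`) additionally doubles the upsampled values, for
the alternative reading of the fusion rule in which the factor 2 multiplies
the term rather than naming the resolution change; the default treats it as
resolution doubling only.

## Deformable transformer

The three coarsest fused scales are flattened (scale-major, H-fastest
raster order) into a token sequence of width $C$ = `fpn_channels`. Each
token receives a 3D sinusoidal positional encoding: for each axis,
$\mathrm{PE}(\mathit{pos}, 2k) = \sin(\mathit{pos}\cdot v)$ and
$\mathrm{PE}(\mathit{pos}, 2k+1) = \cos(\mathit{pos}\cdot v)$ with
$v = 1/10000^{2k/(C/3)}$, the three per-axis tables (each $C/3$ wide)
concatenated and **added** to the token at the transformer input (input
only, not per layer). When $C$ is not divisible by 6 the remainder channels
are zero.

Each DeTrans layer is pre-norm:
$x \leftarrow x + \mathrm{Attn}(\mathrm{LN}(x))$, then
$x \leftarrow x + \mathrm{FFN}(\mathrm{LN}(x))$. The attention is
*deformable*: each query predicts, per head, `n_points` continuous offsets
around its reference location in every tokenized scale plus attention
weights softmax-normalized over (scales $\times$ points), and aggregates
value features sampled trilinearly at those locations. Cost is therefore
linear in sequence length. Offset and weight heads start at zero (sampling
begins at the reference location with uniform weights) and the output
projection starts at zero, the stable-start convention of deformable
attention. Defaults: 4 layers, 6 heads, 4 points, FFN width $4C$.

## Decoder

Token sequences are reshaped back to their grids (the exact inverse of the
flattening raster) and the decoder walks the pyramid coarse-to-fine: a
$2^3$/stride-2 transpose convolution doubles resolution, the fused skip at
that size is concatenated and projected ($1^3$), and one residual block
refines. Decoder widths taper from `fpn_channels` down to `base_channels`.
Output resolution is the *native* patch resolution; the shallow branch's
double-resolution map is folded into the final skip by average pooling.
A $1^3$ head emits single-channel logits; the sigmoid lives outside the
network.

## Ablation switches

`use_transformer = FALSE` routes the fused pyramid straight to the decoder;
`multi_resolution_input = FALSE` feeds the native-resolution patch to both
backbones. These reproduce, at toy scale, the two ablation arms reported
for the architecture (both arms lose accuracy at clinical scale; the
package's acceptance checks test the *direction* of the effect only).

# Pipeline

**Preprocessing.** CT intensities are truncated to $[-1024, 3068]$ HU and
min-max normalized with those *fixed* bounds (not per-volume extrema), so a
given HU value means the same thing in every scan. Volumes are resampled to
uniform spacing (default isotropic 1 mm, configurable; windowed-sinc
interpolation for images — Lanczos-3, anti-aliased when minifying — and
nearest-neighbour for masks, which keeps them binary). Output dimensions
follow $\mathrm{round}(n \cdot s_{\mathrm{in}} / s_{\mathrm{out}})$.

**Patch sampling.** Four random $96^3$ patches per volume per epoch, with
probability `fg_fraction` (default 0.5) centred on a random foreground
voxel: GTVs occupy $\sim10^{-3}$ of a chest volume, and unbiased cropping
would starve the loss of foreground. Volumes smaller than the patch are
symmetrically zero-padded (0 = air after normalization).

**Augmentation.** The nine training-time transforms — rotation
($\pm30^\circ$ about a random grid plane), isotropic scaling (0.85--1.25),
axis flips, Gaussian noise (sd 0.01--0.1 of the normalized range), Gaussian
blur ($\sigma$ 0.5--1.5 voxels), additive brightness ($\pm0.1$),
contrast scaling about the mean (0.75--1.25), low-resolution simulation
(downsample by 1--2$\times$ and back), and gamma transformation
(0.7--1.5) — run spatial-first so injected noise is never interpolated.
Spatial transforms act identically on image and mask (mask by
nearest-neighbour); intensity transforms touch the image only; output is
clipped back to $[0,1]$. The magnitudes are the package's own defaults in
the nnU-Net tradition; the architecture source names the transforms but not
their parameters. "Brightness and contrast adjustment" is implemented as
two independent transforms.

**Loss and optimizer.** Soft Dice plus voxel-mean binary cross-entropy on
logits — the class-imbalance-robust pairing that makes the evaluation
metric the optimization surrogate; the training protocol's stated elements
are SGD, initial learning rate $10^{-3}$, batch size 1, 4 patches/volume,
1000 epochs. Momentum 0.99 (Nesterov), weight decay $3\times10^{-5}$,
polynomial decay (power 0.9), and gradient clipping at norm 12 are the
package's choices where the protocol is silent. A non-finite loss aborts
with a diagnostic rather than training through NaNs. One "epoch" is one
pass over the training volumes (4 patch-steps each); the 90/10
case-level validation split is seeded.

**Inference.** Whole volumes are tiled with overlapping windows (default
overlap 0.5), sigmoid probabilities are averaged in overlaps, and the
result is thresholded at 0.5.

**Evaluation.** Dice $2|X\cap Y|/(|X|+|Y|)$ (both-empty defined as 1;
empty-prediction-vs-nonempty 0) and the symmetric Hausdorff distance over
foreground voxel centres in physical mm, from an exact anisotropic
Euclidean distance transform; HD95 replaces each directed maximum with the
95th percentile of the directed distance distribution. An empty mask makes
HD undefined; it is reported as `NA` (never silently 0 or $\infty$) so
aggregate means are not polluted. Cases are split by the 6-connected
component count of the reference into single- versus multiple-tumor strata,
with per-lesion metrics after maximal-overlap matching of predicted to
reference components. The printed HD of the reference results carries no
units; this package reports physical mm by default with voxel units behind
`spacing = c(1, 1, 1)`.

# The phantom generator

All tests and acceptance checks run on synthetic lung-CT phantoms: a
soft-tissue body ellipsoid (+40 HU) in air ($-1000$), two lung ellipsoids
($-800$), and 1--3 axis-aligned tumor ellipsoids (0--100 HU) placed fully
inside a lung with non-overlapping conservative support checks, plus
additive Gaussian noise on the image only. The mask is the exact geometric
union of the tumor ellipsoids, so it is invariant to noise, and
$\tfrac43\pi r_x r_y r_z$ gives an analytic volume oracle. Default
generator conditions mirror the target imaging setting: in-plane spacing
1 mm with slice thickness 1--3 mm, and tumor radii 3--25 mm so the
generated volumes span sub-cc through $>50$ cc — the clinical size range.
What the phantoms deliberately lack: realistic texture, pleural/vessel
attachment, respiratory motion, and reconstruction physics. Passing tests
therefore demonstrate that the pipeline is *correct* (shapes, geometry,
metrics, convergence), not that the trained toy models would transfer to
clinical CT.

# Numerical engineering

No deep-learning framework is used: the package carries its own
reverse-mode autograd (a tape over R arrays) and C++ kernels for the hot
operations — direct 3D convolution with a vectorizer-friendly K-tap
correlation inner loop and 4-wide output-channel blocking (im2col+GEMM is
far below peak at the 8--32 channel widths used here), pointwise
convolutions routed through BLAS, instance normalization, trilinear
resizing, and border-clamped trilinear grid sampling with gradients to both
features and coordinates. Every primitive's gradient is checked against
central finite differences in the test suite. All computation is double
precision and single-threaded, hence bit-reproducible for a fixed seed;
non-finite sampling coordinates clamp to the border so a diverging run
fails at the loss check, not in a kernel.

# Problem sizes used in the checks

The architecture checks and training demonstrations are deliberately small,
chosen once as the package's standard verification conditions:

* metric-oracle equivalence: 1000 random mask pairs on grids up to
  $10^3$ voxels, against $O(n^2)$ brute force;
* shape/identity contracts: full-size $96^3$ forward pass at reduced width
  (`base_channels = 8`), plus $16^3$/$32^3$ property sweeps;
* overfit demonstration: a reduced model (`base_channels = 8`, 2 DeTrans
  layers) trained with the stated protocol (SGD, $10^{-3}$, batch 1,
  4 patches/volume, Dice+BCE, no augmentation) on five noise-free
  single-tumor phantoms of $32^3$ voxels at 2 mm spacing (tumor radii
  5--9 mm), stopping when training-set Dice exceeds 0.90;
* ablation direction: twenty mixed-size test phantoms of $16^3$ voxels at
  2.5 mm spacing, three seeds per arm, short training runs of the full,
  transformer-less, and single-resolution models under identical
  conditions.

# Known limitations

* Transpose convolutions are restricted to kernel = stride (checkerboard-
  free); general fractionally-strided kernels are not implemented.
* Patches must be cubes with edges divisible by 16 (the stride ladder);
  non-cubic *volumes* are fine — tiling handles them.
* The deformable attention samples from the tokenized scales only; no
  learned-query cross-attention decoding.
* Training at the reference scale (hundreds of clinical volumes, $96^3$
  patches, 1000 epochs) is far outside a single-CPU R session; the training
  loop is demonstrably correct at toy scale and architecturally faithful,
  but the package does not claim clinical-scale accuracy numbers.
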