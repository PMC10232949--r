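---
title: "Methods: attention-gated U-Net for prostate zonal segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-gated U-Net for prostate zonal segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

T2-weighted prostate MRI is the reference modality for assessing the zonal
anatomy of the gland: the inner transition zone (TZ) around the urethra and
the posterior peripheral zone (PZ), where most cancers arise. Delineating
both zones slice by slice is slow and operator-dependent, which motivates
automatic segmentation. `masunet` implements an encoder-decoder
convolutional network for this task and everything needed to train and
evaluate it: losses, metrics, NIfTI data handling in the Medical
Segmentation Decathlon (MSD) layout, offline augmentation, and a synthetic
phantom generator so the entire pipeline runs end-to-end with no external
download.

The whole network — forward and backward passes, Adam, every layer — is
implemented in this package (R with C++ kernels for the convolutions via
`RcppArmadillo`'s im2col + BLAS route). There is no dependency on a
deep-learning framework, which keeps the arithmetic inspectable and lets the
test suite verify every gradient against finite differences.

## The model

The network is U-shaped with four 2x downsamplings, so inputs must have
height and width divisible by 16.

**Encoder.** Five convolution blocks with widths `b, 2b, 4b, 8b, 16b`
(default `b = 64`; `b = 8` for CPU-scale work), each block two rounds of
(3x3 convolution, same padding → group normalization → ReLU), with 2x2
max pooling between them. The fifth block appends channel dropout with
p = 0.5 to curb overfitting in the deepest stage. Group normalization (GN)
is used instead of batch normalization because the training batch is small
(4 slices): GN statistics are per-sample, over channel groups, so they do
not degrade with batch size. The default group count is 8 (all default
widths are divisible by 8); layers narrower than 8 channels fall back to a
single group, i.e. layer normalization over channels. GN epsilon is 1e-5.

**ASPP bottleneck.** Atrous spatial pyramid pooling after the fifth block:
four parallel 3x3 dilated convolutions with rates 1, 6, 12 and 18, each
padded by its rate so resolution is preserved and each followed by GN +
ReLU. Each branch outputs a quarter of the input width, the concatenation
restores it, and a 1x1 convolution fuses the branches back to the
bottleneck width. The rate-1 branch is an ordinary 3x3 convolution; a 1x1
variant was considered but the multi-rate design reads most naturally as
four dilated 3x3 kernels, and the choice is exposed through the branch
configuration rather than hard-coded.

**Decoder.** Four scales of: nearest-neighbour 2x upsampling followed by a
3x3 convolution + GN + ReLU that halves the channels (the "up-conv" block);
an attention gate on the skip connection; concatenation of the gated skip
with the decoder feature; and a convolution block at the first three scales.
At the fourth (full-resolution) scale the concatenation feeds a 1x1 output
convolution directly — the architecture deliberately has three decoder
convolution blocks for four scales, and this wiring is the only one
consistent with that census. The output has one channel per zone (PZ, TZ),
trained as independent sigmoids; background is implicit. A softmax head
would force exclusivity, but the per-channel binary formulation is what a
BCE-based compound loss presumes.

**Attention gate.** Each skip feature `x` is modulated by two coefficients
computed against a gating feature `g`, taken here as the decoder feature
*after* up-convolution so `x` and `g` share both resolution and channel
count — the only wiring under which the gate's two branches are both
well-formed, since the spatial branch adds `x` and `g` pixelwise and the
channel branch adds their pooled vectors elementwise:

- spatial: `alpha = sigmoid(W2(relu(Wx x + Wg g)))`, a one-channel map in
  (0,1), from 1x1 convolutions `Wx, Wg` into an intermediate width
  `F_int = C/2` and `W2` down to one channel;
- channel: `beta = sigmoid(W1(W0(relu(gap(x) + gap(g)))))`, a per-channel
  vector in (0,1), where `gap` is global average pooling and `W0, W1` form
  a bottleneck of width `C/16` (capped at `C` for narrow test networks).

The gated skip is `alpha * beta * x` with the obvious broadcasts, so the
gate can only attenuate. Note the channel branch applies ReLU to the pooled
sum and then the two linear maps back-to-back; the conventional
squeeze-excitation order `W1(relu(W0(.)))` is available behind the
`se_order` flag, but the default follows the formulation above. All five
maps carry biases — the pure linear reading would make the saturation
behaviour of the sigmoids unreachable and is not standard practice.

**Initialization.** Kaiming-uniform for all convolution kernels
(`bound = sqrt(6/fan_in)`), zero biases, GN gamma = 1 and beta = 0. Building
a network is a pure function of (configuration, seed).

## Losses and metrics

Training uses the BCE-dice compound loss on the two sigmoid channels:
mean per-pixel binary cross-entropy (computed stably from logits) plus the
soft dice loss `1 - mean_c (2 Σ p t + s)/(Σ p + Σ t + s)` with smoothing
`s = 1`, equally weighted. The classic pixel-wise softmax field and
weighted cross-entropy `E = -Σ w(x) log p_l(x)(x)` are implemented as well
(the cross-entropy is written with the explicit minus sign so it is
nonnegative, and probabilities are floored at 1e-12); the weight map
defaults to 1 and is not used by the compound training loss.

Evaluation reports Dice `2|A∩B|/(|A|+|B|)`, positive predictive value
`|A∩B|/|A|` and sensitivity `|A∩B|/|B|` per class. Pixel counts are pooled
over all slices of a volume and the metrics computed once per volume per
class, then averaged over volumes; this keeps slices without a zone from
poisoning means, and two empty masks score 1 by convention. Per-slice and
globally-pooled aggregation can be recovered by calling the metric
functions directly on the corresponding arrays. The Dice denominator is
the standard mask-size sum — a union denominator would allow values above
one, contradicting the metric's [0, 1] range.

## Data pipeline

**Loading.** MSD-style NIfTI volumes (4-D image with the modality axis
last — T2 then ADC — or plain 3-D; 3-D integer labels with codes 0
background, 1 PZ, 2 TZ), with a `dataset.json` manifest. The label code map
is taken from the manifest rather than hard-coded. Only the T2 channel is
used by default: the source data's ADC channel has a four times coarser
in-plane resolution and no stated fusion scheme, so multi-modal input is
left as an explicit option (`in_channels = 2`).

**Preprocessing.** Per-volume z-score normalization (clipped to ±5) of the
selected channels, bilinear resizing of image slices and nearest-neighbour
resizing of labels to a uniform size divisible by 16 (256x256 is a
realistic default; the tests and examples use 64x64 to stay CPU-friendly),
and expansion of the integer label into disjoint per-class binary masks.

**Augmentation.** Offline, per slice: each original emits two augmented
copies (tripling the training set), each applying a random subset of
horizontal/vertical flips, rotation (±15°, bilinear for images, nearest for
masks, mirror padding), Gaussian noise (sd 1–5% of the image sd), and
brightness/contrast scaling (factors 0.8–1.2). Geometric transforms are
applied identically to image and masks; intensity transforms touch only the
image. Rotation is implemented in-package as an inverse-mapped sampler
because the paired mask transform requires nearest-neighbour sampling with
mirror padding about the same centre, which the available image libraries
do not expose as one operation.

**Split.** 80/20 by volume (never by slice), labeled volumes only, so no
subject leaks across sets; augmented copies are generated from training
volumes only and validation always sees original images.

**Phantom generator.** The synthetic stand-in for real data draws, per
volume, a PZ outer ellipse and a concentric TZ inner ellipse at 45–60% of
its axes (TZ strictly inside the gland, labels disjoint by construction),
tapers both through-plane like a gland, jitters geometry per slice and per
volume, and adds Gaussian noise. T2-like contrast is TZ (0.80) > PZ (0.50)
> background (0.20) with noise sd 0.05 — a strong but not trivial contrast,
chosen once as representative of the high soft-tissue contrast of T2
imaging; an ADC-like second channel inverts the contrast. Defaults are 10
volumes of 15 slices at 64x64. What the phantom does *not* emulate:
anatomical shape variability beyond ellipses, intensity inhomogeneity
(bias fields), partial-volume boundaries, rectal-coil artefacts. Passing
tests on phantoms therefore demonstrate that the implementation optimizes
and segments correctly, not that the architecture reaches any particular
accuracy on clinical MRI.

## Training

The training recipe follows the published hyperparameters: BCE-dice loss,
Adam, learning rate 3e-4, weight decay 1e-4, batch size 4, at most 1000
epochs, early stopping with patience 20. The recipe lists both Adam and a
momentum of 0.9; Adam has no classical momentum knob, so this is read as
beta1 = 0.9 (an SGD-momentum alternative is available via
`optimizer = "sgd"`). Validation runs once per epoch; the monitored score
is the validation mean Dice (mean of the two zones, pooled per volume) and
the best-scoring weights are retained. Improvement means exceeding the best
score by more than 1e-6. The learning rate is constant — no schedule is
specified and none is invented. All randomness (initialization, shuffling,
dropout, augmentation, phantom geometry) is governed by explicit seeds and
runs reproduce bitwise on one machine.

On a 4-slice, 64x64, `base_channels = 8` overfit run under this exact
recipe, both zones' training Dice climbs steadily over the first few
hundred optimizer steps, with the residual eventually confined to the
1-pixel zone boundaries; `scripts/acceptance.R` reports this run's Dice at
200 and at 600 steps, and the exact trajectory depends on the drawn phantom
geometry (thin PZ rings have proportionally more boundary pixels and
converge later). The step count is governed by the recipe rather than the
implementation: with Adam the per-weight movement after `k` steps is
bounded by about `k * lr`, so early-step Dice is a property of the
learning rate, not of code quality.

## Numerical choices and degenerate inputs

- GN uses population variance and epsilon inside the square root, exactly
  as defined; constant inputs normalize to beta.
- BCE is computed from logits as `log(1 + exp(-|z|)) + max(z, 0) - z t` to
  avoid overflow; the softmax subtracts the per-pixel maximum.
- Max pooling requires even spatial dims and errors otherwise (inputs are
  expected padded/resized to multiples of 16); ties take the first maximum
  in column-major order.
- Empty masks: both empty scores 1 for all three metrics; empty prediction
  against nonempty truth scores 0 PPV/Dice/sensitivity as appropriate.
- Mask prediction thresholds each sigmoid channel at 0.5 (configurable);
  where both classes fire, the rendered label takes the higher probability.
- Checkpoints store the parameter archive plus a JSON sidecar of the
  architecture configuration and build seed, validated on load.

## Problem sizes used in tests

The test suite exercises gradient checks on 16x16 inputs with a
2-channel-base network, end-to-end training on 32x32/64x64 phantom slices,
and forward shape contracts up to 256x256; these sizes were chosen so the
whole suite runs comfortably on one CPU while still covering every code
path at realistic aspect ratios.

## Known limitations

- 2-D slice-wise segmentation only; no 3-D convolutions or through-plane
  context beyond per-volume normalization.
- No bias-field correction or T2/ADC registration; multi-modal fusion is a
  configuration option without a validated scheme.
- The phantom's simplicity means phantom Dice values say nothing about
  clinical accuracy (see above).
- Training is single-threaded CPU; the implementation favours clarity and
  verifiability over speed, and large-scale (base 64, 256x256) training is
  out of its intended range.
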