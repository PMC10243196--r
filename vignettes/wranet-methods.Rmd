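---
title: "Motion deblurring and crop/weed segmentation with WRA-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion deblurring and crop/weed segmentation with WRA-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cameras on field robots and hand-held platforms move during exposure, so
crop/weed images frequently arrive motion-blurred. Blur destroys the fine
leaf boundaries that a semantic segmentation model needs to separate crop
from weed from soil, and segmentation accuracy drops accordingly. This
package implements a two-stage answer: first restore the blurred image with
a dedicated deblurring network (WRA-Net), then segment the restored image
with a standard U-Net into three classes (background = 0, crop = 1,
weed = 2).

## The restoration model

WRA-Net is an encoder–decoder residual network operating on images scaled
to the model domain $[-1, 1]$.

**Encoder.** Conv Block 1 (two 3×3 convolutions, 3 → C → C channels, each
followed by instance normalization and ReLU) lifts the RGB input to C
feature channels. Each encoder level then applies a *Lite wide receptive
field attention residual block* (Lite WRARB) and Conv Block 2 (3×3 conv +
instance norm + ReLU), whose output is the level's skip connection to the
decoder; a 2×2 stride-2 convolution halves the resolution between levels.
Instance normalization is used throughout the encoder because training runs
on small patches with small batches, where batch statistics are unreliable;
the decoder uses batch normalization — this mixed placement is the
configuration that performed best in ablation.

**Lite WRARB.** The input is processed by four parallel *mDSCB groups*.
One mDSCB is a depthwise-separable block: a pointwise 1×1 convolution
(C → C) followed by a per-channel 3×3 depthwise convolution, instance norm
and ReLU — $C^2 + 9C$ convolution weights instead of the $9C^2$ of a full
3×3 layer. Group $n$ chains $n$ mDSCBs and therefore contributes an
effective receptive field of $(1 + 2n)$; with the default groups
$\{1,2,3,4\}$ the concatenated 4C-channel features mix receptive fields
from 3×3 up to 9×9. A pointwise fusion convolution returns to C channels,
a pointwise attention gate
$\sigma(\mathrm{Conv}_{1\times1}(\mathrm{ReLU}(\mathrm{Conv}_{1\times1}(F))))$
re-weights every feature in $(0,1)$, and a *learnable skip*
$F_{att} + \alpha \circ x$ adds the block input scaled per channel by
$\alpha$, initialized to zero so a fresh block passes only its attention
branch.

**Decoder.** Each decoder level expands the previous level's features
1×1 to 4C channels, pixelshuffles them (an exact channel-to-space
permutation) to C channels at doubled resolution, concatenates the
encoder skip, and fuses with a 3×3 convolution + batch norm + ReLU.
A *Deformable ResBlock* follows:
$\mathrm{Conv}_{3\times3}(\mathrm{ReLU}(\mathrm{DeformConv}_{3\times3}(F))) + F$,
where the deformable convolution samples its nine taps at learned
continuous offsets with per-tap multiplicative modulation (bilinear
interpolation). The offset/modulation predictor is zero-initialized and the
modulation is $2\,\sigma(\cdot)$, so at initialization the block equals a
plain convolution residual block exactly — this stabilizes early training
and gives the test suite a standard-convolution oracle. Conv Block 3
narrows C → C/2 → C/4 → 3, and the output is
$\tanh(F_{res} + I_{blur})$: the network learns a residual and the tanh
keeps every output strictly inside $(-1, 1)$. With Conv Block 3's last
layer zero-initialized (the default), a fresh network is exactly
$\tanh(\cdot)$.

Depth is configurable (`levels`, default 3; spatial dims must be divisible
by $2^{levels-1}$) and the width C (default 128) is constant across levels.
The deepest encoder output serves directly as the decoder's starting
features; no extra bottleneck blocks are inserted. The attention gate's
hidden width equals C and its pointwise convolutions carry biases;
convolutions inside mDSCB are bias-free (a normalization follows
immediately), all others carry biases. These choices fix the closed-form
parameter count asserted by `wranet_param_formula()`.

## Losses and metrics

Restoration trains with the composite loss
$\lambda_1 (1 - \mathrm{SSIM}) + (1 - \lambda_1)\,\|\cdot\|_1$ with
$\lambda_1 = 0.84$. SSIM uses stabilizers $m = 2.55$ and $n = 7.5$, which
are calibrated for the 0–255 intensity scale, so the SSIM term is computed
after the affine de-normalization $(x + 1) \cdot 127.5$; the L1 term is the
mean absolute difference in the model domain. The SSIM used in the loss and
the reported metric is the windowed form (11×11 Gaussian window,
$\sigma = 1.5$), averaged over the local SSIM map; a global-statistics mode
exists for closed-form oracle tests. Window statistics are renormalized by
the window's in-bounds mass at image borders, so a constant image has
exactly uniform statistics and the windowed value coincides with the
$\sigma = 0$ closed form — this also keeps the loss differentiable through
the border handling.

The segmenter is the canonical 4-stage U-Net with two amendments that
desk-scale training made necessary and that match common modern usage:
batch normalization inside every double-convolution block, and a
zero-initialized 1×1 classifier head. Without normalization, Adam's
uniform per-parameter steps coherently inflate the gain of every layer of
the norm-free network — activations grow multiplicatively across its ~20
convolutions — and the softmax saturates to the majority class within a
few dozen steps at any learning rate, after which the rare-class gradients
are exponentially dead. Batch norm pins the activation scale and removes
the runaway; the zero-init head starts training from uniform class
probabilities, where the class-balanced Dice gradients are strongest.

The segmenter trains with Dice loss over the three classes,
$1 - \frac{1}{Cls}\sum_c \frac{2\sum_i P_{ci} L_{ci} + \epsilon}
{\sum_i (P_{ci} + L_{ci}) + \epsilon}$ with $\epsilon = 10^{-6}$ guarding
empty classes. Evaluation reports PSNR ($10 \log_{10}(255^2 / MSE)$, MSE
averaged over all pixels and channels, dynamic-range reading of the
maximum), per-class IOU $TP/(TP+FP+FN)$, their unweighted mean mIOU
(background included), macro-averaged recall and precision, and the F1
computed from those macro averages. A class absent from both maps
contributes 1 (vacuous truth) rather than NaN; affected classes are listed
in the returned object.

## Training protocol

Two stages. Stage 1 optimizes WRA-Net with Adam ($\beta = (0.9, 0.999)$,
defaults), initial learning rate $10^{-4}$ annealed per optimizer step with
a cosine schedule (no restarts) to $10^{-7}$, batch size 2, random aligned
256×256 crops, 450 epochs. Stage 2 freezes the restorer — it is only ever
executed in inference mode, so its weights are bit-identical before and
after — and trains the U-Net on restored crops with Dice loss and Adam at
$10^{-5}$. The validation split takes the last 10 % of records in manifest
order. No gradient clipping and no augmentation beyond the random crops.
Validation loss is computed on full held-out frames rather than crops.

## Synthetic study conditions

No field datasets ship with the package; a generator supplies both sides of
the problem.

*Blur.* Camera shake is modeled as a momentum random walk: velocity
$v_{t+1} = 0.7\,v_t + \mathcal{N}(0, 1)$ over 64 steps, positions
recentred, auto-rescaled (never clipped, so no mass is lost) onto a 33×33
canvas and splatted with bilinear weights into a unit-sum point-spread
function. Images are convolved per channel under symmetric
(edge-inclusive) reflection padding, which preserves constant images
exactly and never increases variance. On 64×64 synthetic scenes this
default blur costs roughly 25 dB PSNR against the sharp originals — the
same severity regime as the no-restoration baseline reported for real
motion-blurred field data — so the scaled-down experiments below probe the
method under a realistic degradation level.

*Scenes.* A soil-colored background with smoothed Gaussian texture carries
`n_crops` larger green leafy clusters (class 1) and `n_weeds` smaller
yellow-green blobs (class 2). Each plant is a union of ellipses through a
common center, so it is one connected component; objects are placed with a
minimum separation (bounded retries), which makes component counts exact
and labels match the rendered masks pixel for pixel. The generator is
deterministic given its seed. What it does *not* emulate: photorealistic
leaf venation and occlusion, camera sensor noise, illumination gradients,
or class-imbalance extremes of real plots — passing tests demonstrate that
the algorithms and training dynamics behave as specified, not field-level
accuracy.

## Scaled-down experiments

The reference protocol (C = 128, 256×256 crops, 450 epochs) is far beyond a
single CPU, so the package's own experiments shrink the problem rather than
the claims, and the test suite states the sizes it uses:

* *Learning check*: a C = 8, levels = 2 restorer trained 200 Adam steps on
  eight 64×64 blurred/sharp pairs, evaluated on four held-out pairs.
  At this step budget the reference learning rate $10^{-4}$ barely moves
  the weights, so the scaled-down runs use $10^{-2}$ annealed to $10^{-3}$ —
  the same schedule shape, compressed. The training loss falls reliably and
  the run replays bit-identically under its seed. One honest limitation is
  worth stating plainly: at 200 steps the tiny model recovers almost all of
  the pointwise tanh correction of the output layer (a perfect pointwise
  correction can only tie the blurred input's PSNR, since atanh inverts the
  output tanh exactly), lifting held-out PSNR clearly above the passthrough
  initialization, but spatial deblurring gains do not yet generalize from
  eight pairs: held-out restored PSNR approaches the blurred baseline to
  within about 0.15 dB without crossing it. At gentler learning rates the
  training set does cross its own baseline while held-out data lags
  further — classic overfitting to the eight scenes and their blur
  kernels. Crossing on held-out data needs more pairs or more steps than
  this protocol allows.
* *Scheme harness*: the five train/test combinations of
  original/blurred/restored data (Scheme 1 = sharp/sharp, 2 = sharp/blurred,
  3 = blurred/blurred, 4 = sharp/restored, 5 = restored/restored) run with
  a base-8 U-Net (Dice, learning rate $3 \times 10^{-3}$ at this scale,
  300 steps over 48×48 crops) on 64×64 scenes, several seeds. The
  qualitative ordering expected — and asserted on the seed average — is
  clean ≥ restored-consistent ≥ blur-mismatched:
  mIOU(S1) ≥ mIOU(S5) ≥ mIOU(S2).

Package defaults are untouched by the scaled-down settings and remain the
reference values (asserted in the suite).

## Numerical choices

* All tensors are `(H, W, C, N)` double arrays; convolutions run as
  compiled im2col + BLAS GEMM; gradients come from a small reverse-mode
  tape whose per-layer backward rules are validated against central
  differences in the test suite.
* 3×3 convolutions use zero padding 1; the 2×2 downsampling convolution is
  exact halving (even dims are enforced).
* Instance norm tracks no running statistics; batch norm keeps running
  means/variances (momentum 0.1) for inference mode. Both use
  $\epsilon = 10^{-5}$.
* Argmax labelling breaks ties toward the lowest class index, so a uniform
  probability map is all background, deterministically.
* Tiled inference uses patch 256 / stride 128 by default with uniform
  overlap averaging; the input is mirror-extended (edge-inclusive), which
  stays defined when the padding exceeds the image, so images smaller than
  one patch run as a single padded tile. With the zero-initialized output
  layer the whole pipeline is an exact $\tanh$ passthrough, which the
  suite uses to prove seam-freeness.
* PSNR of identical images is reported as `Inf` rather than an arbitrary
  cap.

## Known limitations

Training at the reference scale (C = 128, 450 epochs) is impractical in
this R implementation — it targets correctness, testability and
desk-scale experiments, not GPU throughput. The synthetic scenes are
deliberately simple; results on them bound what the implementation can
show about real field imagery. Restoration quality at very large blur
kernels (approaching the image size) is untested, and the segmenter is the
canonical U-Net only — no alternative backbones.
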