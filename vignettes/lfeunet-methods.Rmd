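---
title: "Lightweight full-encoder U-shaped segmentation: models, losses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight full-encoder U-shaped segmentation: models, losses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfeunet)
```

## The model

`lfeunet` implements a lightweight full-encoder U-shaped convolutional
network (LFE-UNet) for 2D semantic segmentation of medical images: a
contracting encoder of $N$ levels whose level-$i$ feature maps carry
$2^{i-1} n$ channels (with a very small base width, $n = 8$ by default), and
$N-1$ decoder levels that each receive resampled feature maps from *every*
encoder level — not only the same-scale one, as in the classic U-Net.

Decoder level $i$ works as follows. Every encoder feature map
$X^j_{\mathrm{En}}$, $j = 1, \dots, N$, is brought to scale $i$ (max pooling
with a non-overlapping $2^{i-j}$ window when moving deeper, bilinear
interpolation with half-pixel centres when moving shallower), and the
next-deeper decoder output $X^{i+1}_{\mathrm{De}}$ is upsampled to the same
scale. Each branch passes through its own single $3\times3$ adapter
convolution $\Gamma$ that maps it to the decoder's own width
$d_i = 2^{i-1} n$; the branches are concatenated and fused by
$\Theta$ — two $3\times3$ convolutions, each followed by batch
normalisation and a ReLU — whose output again has $d_i$ channels, mirroring
the encoder. A $1\times1$ convolution projects the level-1 decoder output to
the class scores.

Two structural points deserve emphasis because they are what makes the
published parameter table reproducible:

* **The bottleneck is shared.** The level-$N$ node is the encoder output
  itself; decoders exist at levels $1, \dots, N-1$. At level $N-1$ the
  "next-deeper decoder" *is* the bottleneck, i.e. encoder level $N$, which
  already sits among the $N$ full-encoder branches — so that level
  aggregates $N$ branches, while all shallower levels aggregate $N+1$.
* **Only convolution weights are trainable.** Convolutions carry no bias
  term and batch normalisation carries no learnable affine parameters
  (it purely standardises per channel). Under this convention the
  closed-form counts, the empirical enumeration of the constructed network,
  and the published per-configuration totals agree exactly; adding biases
  or affine terms breaks the 3-decimal agreement (e.g. 0.895 M instead of
  0.892 M for $N=5$, $n=8$).

Two backbones are provided:

* **vgg16-style** — two $3\times3$ convolutions per stage at widths
  $n, 2n, 4n, \dots$, max pooling between stages. This "two convolutions per
  stage" layout (rather than the canonical 13-convolution VGG16 stack) is
  the one that reproduces the published counts across the whole
  $N \in \{3..6\} \times n \in \{8,16,32,64\}$ grid; the deeper grid rows
  simply continue the width doubling ($32n$ at level 6).
* **resnet34-style** — a stride-1 $3\times3$ stem at width $n$ (level 1),
  then four stages of residual basic blocks with block counts
  $w = [3, 4, 6, 3]$ at widths $2n, 4n, 8n, 16n$; the first block of every
  stage downsamples with stride 2 and carries a $1\times1$ projection
  shortcut. With 12 input channels and 4 classes this model counts
  1,926,400 parameters — the published 1.93 M; omitting the projection
  shortcuts would give 1.92 M, which is how we fixed that convention.

`closed_form_params()` evaluates the count analytically from the
configuration; `empirical_params()` enumerates the constructed layers. The
two are independent routes and the test suite requires exact agreement over
the full grid.

## Losses

Nine losses are implemented (`compute_loss()`), with weighted combinations
(`combine_loss()`) and the `dfk_loss()` preset (Dice + focal + KL, the
combination used for the headline results). Conventions the source
formulations leave open, fixed here and validated against an independently
coded per-pixel oracle in the tests:

* Class probabilities come from a softmax over the class dimension; BCL
  applies an elementwise sigmoid to raw scores, and BCE is the only loss
  that demands probabilities as input (it rejects anything outside $(0,1)$).
* Dice and Tversky use a smoothing constant $10^{-6}$ in numerator and
  denominator, are computed per sample and class, and average over both.
  Tversky weighs false positives with $\alpha = 0.3$ and false negatives
  with $\beta = 0.7$; at $\alpha = \beta = 0.5$ it coincides with the Dice
  loss up to the smoothing constant.
* The focal loss uses balance $\lambda = 0.25$ and exponent $\gamma = 2$;
  at $\gamma = 0$, $\lambda = 1$ it equals cross entropy exactly.
* KL divergence is taken against an $\epsilon$-smoothed one-hot target
  ($\epsilon = 10^{-8}$) to avoid $\log 0$; its gradient then coincides
  with the cross-entropy gradient up to the smoothing.
* "Smooth F1" is read as a soft (differentiable) macro F1 computed per
  class over the whole batch, $1 - \mathrm{softF1}$. This reading is
  provisional — the source presentation of that formula is not fully
  recoverable — and is the one place where our implementation is a
  best-effort interpretation. "L2" is the mean squared error between the
  softmax output and the one-hot target.
* Combination weights default to an unweighted sum, which is how DFK is
  composed. Whether the background class participates in the
  class-averaged overlap losses is configurable
  (`include_background`, default `TRUE`).

Every loss has an analytic gradient with respect to the raw scores
(`lfeunet:::loss_grad`), cross-checked against central differences; the
training engine consumes these directly rather than differentiating
numerically.

## Training engine

`fit_unet()` runs mini-batch Adam with the published setup as defaults:
learning rate $10^{-4}$, weight decay $2 \times 10^{-3}$, batch size 5, up
to 500 epochs, and a reduce-on-plateau schedule that multiplies the rate by
0.1 after 20 validation epochs without improvement. Decisions where the
source is silent:

* "20 consecutive iterations" is read as 20 *validation epochs* —
  improvement is checked once per epoch, on the validation loss by default
  (switchable to Dice via `monitor = "dice"`).
* Weight decay follows the classic Adam convention (the L2 term is added to
  the gradient before the moment updates), not decoupled decay.
* There is no early stopping beyond the schedule; an optional
  `stop_dice` target can end a run once the best validation Dice reaches a
  requested level, which the test suite uses to keep smoke runs short.
* Bilinear upsampling uses the half-pixel-centre convention
  (`align_corners = FALSE` in common framework terms).
* Weights are Kaiming-initialised ($\mathcal{N}(0, \sqrt{2/\mathrm{fan~in}})$)
  under a caller-provided seed; data order is derived from the training
  seed per epoch, so runs are bit-reproducible.

The whole forward/backward stack (im2col convolutions, non-affine batch
norm, max pooling, bilinear resizing, a minimal reverse-mode tape) is
implemented in this package with RcppArmadillo kernels and is verified
against finite differences for both backbones in the tests.

## Synthetic data

The generators exist so that every module is exercisable end-to-end without
external downloads, at the data *shapes* of the two benchmark tasks:

* `generate_liver_like()` — 3-channel slices with one smooth bright blob
  (an elliptical-harmonic boundary, area calibrated into a configured
  foreground-fraction range, default 10–35%) over a textured background;
  binary labels. Contrasts (background ≈ 0.25, organ ≈ 0.65, texture noise
  sd 0.05) are fixed defaults chosen so that the smallest network
  ($N=5$, $n=8$) learns the task within minutes on a CPU at 64×64.
* `generate_brats_like()` — 12-channel images (four pseudo-modalities of
  three channels, one shared geometry, modality-specific contrasts) and
  4-class labels built from three concentric structures (enhancing core
  inside non-enhancing core inside edema) within a brain-like ellipse, so
  the nested-region mapping `map_nested_regions()` is valid by
  construction. Whole-tumor fraction defaults to 6–20%.
* `generate_liver_volume()` — a stack of correlated slices with a
  lens-shaped cross-section profile, for exercising
  `select_prominent_slices()` ("most prominent" is read as the largest
  foreground pixel count per slice; ties break toward the lower index).

What these phantoms deliberately do *not* model: CT Hounsfield statistics,
MRI bias fields, anatomical variability, multiple organs, or ambiguous
boundaries. Passing the smoke-training checks therefore demonstrates that
the architecture, losses, optimiser and bookkeeping interact correctly —
not that the network reaches any particular accuracy on real scans.

## Noise studies

`add_gaussian_image_noise()` adds i.i.d. zero-mean Gaussian noise of a
given variance in the normalised $[0,1]$ intensity space and then clips to
$[0,1]$ (clipping, rather than rescaling, is our documented choice).
`add_saltpepper_label_noise()` interprets the salt-and-pepper "variance" as
the corrupted-pixel *fraction* — the common imaging-toolbox convention —
choosing that fraction of pixels uniformly without replacement and
overwriting half with 1 and half with 0, so the overwrite count is exact
and auditable. `build_noisy_dataset()` degrades images (Gaussian) or
training labels (salt-and-pepper) only; validation labels are never
corrupted, since evaluation is always against the true annotation.

## Evaluation

`dice_coefficient()` implements $2|A \cap B| / (|A| + |B|)$ with the
both-empty case defined as 1. The brain-tumor evaluation maps 4-class
labels to the nested regions WT = ET∪ED∪NET, TC = ET∪NET, ET, computes
per-slice Dice per region, averages each region arithmetically over slices,
and reports the mean of the three region averages (region-averaged, not
sample-weighted).

## Problem sizes used by the checks

The test suite trains the $N=5$, $n=8$ vgg16-backbone model on 200
synthetic liver-like 64×64 slices (90/10 split) with both cross entropy and
DFK, requiring held-out Dice ≥ 0.85 within at most 30 epochs; at a learning
rate of $10^{-3}$ — an appropriate scale for this small, high-contrast
task — the target is typically reached within one or two epochs. The
label-noise study in the tests uses 120 slices and 2 epochs per corruption
level $v_s \in \{0, 0.1, 0.2\}$, and checks that corrupted training labels
do not erode held-out Dice by more than 3 percentage points (in our runs
the noisy-label models match or slightly exceed the clean run — the
dynamic-equilibrium behaviour). Parameter accounting is exercised over the
full published grid, which is cheap because `init = "none"` lays out layer
shapes without allocating weights — this is also how the 245 M-parameter
grid corner stays inexpensive to verify.

## Known limitations

* 2D slices only; no 3D convolutions, attention, pretrained weights or
  multi-GPU training — all outside this package's scope.
* The CPU engine is tuned for small images and the lightweight
  configurations; wide configurations ($n = 64$) are supported for
  parameter accounting but are impractical to train here.
* The "Smooth F1" reading is provisional, as noted above.
* The salt-and-pepper injector is defined for binary labels only.
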