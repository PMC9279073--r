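---
title: "Methods: a dual-attention multiscale fusion network for retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-attention multiscale fusion network for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselnet)
```

## The problem and the model

Segmenting the vessel tree in a fundus photograph is a per-pixel binary
classification problem with two awkward properties: vessels are thin,
curvilinear and low-contrast (especially terminal capillaries), and labelled
data are scarce (the classic DRIVE and STARE benchmarks have 40 and 20
images).  The standard response to both is patch-based training of a fully
convolutional network: small fixed-size crops (64×64 here) are sampled from
the full-resolution images, heavily augmented, and the trained network is
applied to full images by tiled inference.

`vesselnet` implements a compact two-branch fusion architecture built from
three ingredients:

* **C_B_R units** — same-padded 2-D convolution, batch normalization, ReLU.
  The convolutions are bias-free: a batch norm immediately follows every
  convolution and absorbs any constant shift, so a bias would be redundant
  (and its gradient exactly zero).
* **Shuffle Attention (SA)** — the input's `C` channels are split into `G`
  groups; each group is halved.  The first half is gated per channel by
  `sigmoid(w1 * GAP(x) + b1)` where GAP is the spatial mean; the second half
  is gated per pixel by `sigmoid(w2 * GN(x) + b2)` where GN normalizes the
  half-group (its channels and pixels, per sample) to zero mean and unit
  variance.  Gate parameters have length `C/(2G)` and are shared across
  groups.  After the halves are reassembled an inter-group channel shuffle
  (reshape `G × C/G`, transpose, flatten) mixes information between groups.
* **Efficient Channel Attention (ECA)** — channels are gated by a sigmoid of
  a same-padded 1-D convolution across the pooled channel descriptor.  The
  kernel size adapts to the channel count as the odd integer nearest to
  `log2(C)/r + b/r` with `r = 2`, `b = 1` (so 3 for 32 or 64 channels).
* **Block1**, the attention-gated residual unit:
  `y = ReLU(x) + ECA(BN(Conv1x1(ReLU(BN(Conv3x3(x))))))`, shape-preserving.

The wiring for a 64×64×3 patch (shapes H×W×C, all reproduced by
`inspect_taps()`):

| stage | computation | tap |
|---|---|---|
| stem | C_B_R(32,k3) → SA → C_B_R(16,k3) | F1 = 64×64×16 |
| branch A | SA → C_B_R(64,k3,s2) | F4 = 32×32×64 |
| branch B | SA → C_B_R(32,k1,s2) → Block1 → C_B_R(64,k1,s2) | F2 = 16×16×64 |
| F5 | F2 → ECA → upsample ×2 | F5 = 32×32×64 |
| F3 | F2 → Block1 → C_B_R(64,k1) → upsample ×2 | F3 = 32×32×64 |
| fusion | (F4 + F5) concat F3 | F6 = 32×32×128 |
| head | C_B_R(32,k1) → Conv(3,k1) → upsample ×2 → sigmoid | 64×64×3 |

Branch A carries fine-grained, high-resolution features (one stride);
branch B descends two strides through two residual units and re-expands, so
the fusion combines short-range detail with longer-range context.  The
elementwise sum F4 + F5 requires those taps to agree in shape, which pins
the upsample feeding F5 to ×2; the concatenation with F3 pins the factor
ahead of F3 to ×2 as well.  Descriptions of this architecture sometimes
print a stride-4 upsample there; a ×2 factor is the only value consistent
with the declared 32×32×64 shape of F3 and with the fusion, so ×2 is the
default (`f3_upsample_factor`), kept configurable.

Two further points were genuinely open and are resolved as follows:

* **Output head.** The head is described as two C_B_R units (32 and 3
  filters) followed by upsampling, trained with a per-pixel binary
  cross-entropy.  A literal ReLU before the sigmoid would be degenerate —
  `sigmoid` of a non-negative pre-activation can never fall below 0.5, so
  background pixels could never receive a low probability.  And batch
  normalization of the final logits is equally at odds with a probability
  head: it re-centers the logits to (roughly) zero mean every batch, so the
  network cannot hold the strongly negative background logits that the
  class prevalence demands.  The final unit is therefore the standard
  segmentation logits layer: a plain 1×1 convolution with bias, followed by
  the ×2 upsample of the pre-activation and the sigmoid, producing a
  3-channel probability map.  Binary labels are replicated across the 3
  channels for the loss; at inference the vessel probability is the channel
  mean.  A `head_activation = "relu_sigmoid"` variant keeps the literal
  conv → BN → ReLU reading for comparison.
* **SA placement and sharing.** The stem applies SA between the two C_B_R
  units (on 32 channels), as the stated order implies; the three SA modules
  have independent parameters.

## Tunable parameters

* `sa_groups = 8`: SA group count per stage.  The smallest channel count SA
  gates is 16 (branches A/B read the 16-channel F1), giving half-groups of
  a single channel; the stem SA on 32 channels gets 2-channel half-groups.
  Any per-stage values with `C` divisible by `2G` are accepted.
* `eca_r = 2`, `eca_b = 1`: ECA kernel-size constants.  Ties in the
  nearest-odd rule resolve toward the smaller odd value, with a floor of 1.
* SA gates initialize to zero weight and bias — every gate starts at the
  neutral 0.5 and no branch is favoured at the start of training;
  convolutions are He-normal, batch norms start at scale 1 / shift 0.
* Training (`train_control()`): Adam with initial learning rate `0.001`
  multiplied by `0.9` after every epoch, batch size 128, 100 epochs by
  default.  The "decay 0.9" is read as a per-epoch learning-rate factor
  (it is listed beside the initial learning rate); Adam's moment
  coefficients stay at their conventional 0.9/0.999.  Per-pixel binary
  cross-entropy with probabilities clamped at `1e-7`.
* Patch pipeline: training draws 500 random 64×64 patches per image
  (seeded); patches whose field-of-view coverage is below 50% are rejected.
  On-the-fly augmentation applies a random flip or right-angle rotation per
  patch — pure pixel permutations that keep masks binary; `augment()` also
  offers integer translations in [−8, 8] px with zero fill.  Inference
  tiles full images at stride 32 and averages overlapping tile
  probabilities.
* Evaluation counts pixels inside the field of view when a FOV mask exists
  (fundus borders carry no information); `use_fov = FALSE` switches to
  whole-image counting for comparability with tools that do not mask.

## The phantom generator

`generate_phantom()` draws branching vessel trees inside a circular field
of view: trunks start on the FOV periphery pointing inward; segment lengths
are uniform in [10, 30] px, direction changes uniform in [10°, 40°], side
branches appear with probability 0.3 at 0.72× the parent width, and the
trunk tapers by 0.93 per segment from a 5 px root down to 1.2 px.  Each
tree grows against an area budget so that total vessel coverage is ~12% of
the FOV — the order observed in fundus ground truths — which keeps the
vessel fraction stable (< 3 percentage points) across seeds.  Segments are
rasterized with a Gaussian cross-section (σ = width/2) darker than the
background by `vessel_contrast = 0.35`; a smooth illumination ramp
(amplitude 0.15) and Gaussian pixel noise (σ = 0.03) are added.  The ground
truth is the full-width-half-maximum support of the *noiseless* response,
so labels are exact by construction.

What the phantoms do capture: curvilinear branching geometry with endpoints
and crossings, width tapering, low vessel/background contrast, uneven
illumination, a dark border outside a circular FOV, and exact co-registered
masks.  What they do not: optic disc and macula, pathologies (exudates,
hemorrhages), central vessel reflex, JPEG-like texture, or inter-observer
label noise.  Tests passing on phantoms therefore demonstrate that the
architecture, gradients, optimizer and pipeline work end to end — not that
clinical-grade accuracy transfers to real fundus images, which requires the
real benchmarks (see the README's optional workflow).

## Numerical choices

* Group-norm and batch-norm stabilizers are `1e-5`; batch-norm running
  statistics use momentum 0.1 and the unbiased variance.
* Upsampling is bilinear with the half-pixel-center convention
  (output `i` samples input `(i+0.5)/f − 0.5`, edge-clamped); nearest
  neighbour is available.  The backward pass is the exact adjoint.
* Internal activations are stored in single precision by default
  (`network_config(precision = ...)`): master weights, normalization
  statistics and all gradient accumulators remain double, so only the
  activation round-trip is affected (forward agreement with the double
  engine is ~1e-6 on unit-scale inputs).  The exported module functions
  (`shuffle_attention()`, `eca()`, `block1()`, `cbr()`) always compute in
  double, and the analytic backward pass of the double engine is verified
  against central finite differences in the test suite.
* A pixel exactly at the binarization threshold is background (strict
  inequality); stitched pixels covered by no tile are `NA`, never silently
  zero; metrics with a zero denominator are `NA`, never 0/0.
* Degenerate inputs fail loudly: channel counts not divisible by `2G`,
  stride/size mismatches and incompatible tap shapes are rejected at
  configuration time with messages naming the offending taps.

## Scale of the shipped checks

The test suite exercises the full system at sizes chosen for a single CPU:
oracle comparisons use feature maps up to 8 channels and 4×4 pixels
(compared elementwise to hand-written scalar loops at 1e-5); the end-to-end
learning check trains the default 64×64 network on 2,000 patches from 20
phantoms (256×256) for 10 epochs at batch size 128 and asserts validation
accuracy ≥ 0.95 and sensitivity ≥ 0.60 on 5 held-out phantoms — in the
region of, but deliberately below, the headline numbers reported for
100-epoch training on the real benchmarks, which this suite does not claim
to reproduce.

## Known limitations

* The CPU engine is single-threaded; full 100-epoch benchmark training is
  possible but slow (hours), and is the reason the phantom workflow exists.
* BatchNorm couples the samples of a mini-batch, so per-sample streaming
  (which would reduce memory further) is not available.
* The generator's polarity flag covers bright-vessel modalities only in the
  sense of inverted contrast; no attempt is made to model angiography noise.
* `sensitivity`/`specificity` are threshold-dependent; no ROC sweep is
  provided because the method's evaluation protocol fixes the 0.5 threshold.
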