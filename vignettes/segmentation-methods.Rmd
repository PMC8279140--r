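---
title: "Backbone U-Nets for pneumothorax segmentation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone U-Nets for pneumothorax segmentation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumoseg)
```

## The task and the pipeline

Pneumothorax segmentation on frontal chest radiographs is a strongly
imbalanced pixel-labelling problem: roughly a fifth of images carry any
lesion at all, and a positive lesion is a thin lucent crescent occupying a
few percent of the frame. The pipeline implemented here follows the
ensemble-of-backbone-U-Nets design that performed at the top of the SIIM-ACR
challenge field: four encoder–decoder networks with ImageNet-style
classification backbones, BCE-Dice training under cosine annealing with
terminal checkpoint averaging, horizontal-flip test-time augmentation (TTA),
weighted probability-map ensembling, and a dual-threshold post-processing
step tuned by grid search.

This vignette records the scientific and numerical decisions the package
takes, especially where the design space was genuinely open.

## Mask encoding

Annotations are relative run-length encodings over flattened 1,024 × 1,024
masks: token pairs `(offset, length)` where the first offset is an absolute
flat index and subsequent offsets are gaps counted from the end of the
previous run; `-1` is the empty mask.

The format leaves two things unstated that the codec must fix: the
flattening order and the index base. The published worked example has gaps
close to `width - 2` and is consistent with several dialects. We default to
**column-major flattening with 0-based indices**, matching the challenge's
reference encoder, and expose both as arguments (`order`, `base`). The
dialects are conjugate — decoding under one order equals the transpose of
decoding under the other — which the property tests assert explicitly.
Multiple RLE rows per image (about a quarter of positive cases in the real
corpus) are merged by pixelwise OR at load time: they are component
annotations of one condition. Malformed rows fail loudly with the image id;
silently skipping corrupt annotations would bias training prevalences.

## Preprocessing

Images are single-channel 8-bit; they are replicated to three identical
channels (so backbones designed for RGB apply unchanged), resized
bilinearly, and rescaled to [0, 1]. Masks are resized with nearest-neighbour
interpolation only, which provably preserves the value set {0, 1}; binarity
is asserted at every stage boundary in the tests. DICOM inputs are read by a
deliberately narrow single-frame 8-bit reader (the only form the pipeline
consumes); MONOCHROME1 files are inverted to MONOCHROME2 polarity so lesion
contrast always has the same sign.

## Augmentation

The training menu: horizontal flip; shift–scale–rotate with rotations up to
20°; one of elastic, optical or grid distortion; one of random contrast,
brightness or gamma; plus random crops (resized back) for the ResNet50-UNet
recipe only. Application probabilities and distortion magnitudes are not
part of the published recipe, so the package declares conventional defaults
rather than inferring them: every group applies with probability 0.5 (shift
limit 0.0625, scale limit 0.1, uniform choice within each one-of group), and
crops keep 81–100% of the area so lesions mostly stay in frame. All are
plain fields on `augmentation_config()`. Geometric warps are applied
identically to image and mask (the mask via nearest-neighbour sampling, so
it stays binary); intensity transforms touch the image only. Every draw is
keyed to an explicit `rng_state`, making augmentation bitwise reproducible.

## Architectures

Each network is a backbone truncated before global pooling and classifier,
plus five decoder blocks: nearest-neighbour 2× upsampling, concatenation of
the matching-resolution encoder tap (first four blocks), then two 3×3
convolutions with batch normalization and ReLU, channels halving
256 → 16; a 3×3 convolution to one channel and a sigmoid close the network.
The DenseNet-169 variant omits decoder BN (its preset also restores
convolution biases, which BN otherwise subsumes).

**Skip taps.** Which encoder activations feed the skips is not fully
determined by "the corresponding part of the encoder", so the presets record
a concrete, conventional choice:

* ResNet-50 / SE-ResNeXt-50: the stem activation (stride 2) and the outputs
  of the first three residual stages (strides 4, 8, 16);
* DenseNet-169: the stem activation and the transition blocks *after their
  1×1 compression convolution* (pre-pool resolution, halved channels);
* EfficientNet-B4: the expansion activations of the first block of each
  downsampling stage (the features at the pre-downsample resolution).

With these taps the trainable parameter counts are 32.52 M (ResNet50-UNet),
19.36 M (DenseNet169-UNet), 34.52 M (SE-ResNeXt50-UNet) and 25.61 M
(EfficientNetB4-UNet) — all within 1% of the published model sizes, which is
how the tap choice was validated. For DenseNet in particular, tapping
*before* the compression convolution would add ~2 M parameters and leave the
published size unreachable, so the compressed tap is the one the preset
uses.

**Engine.** No deep-learning framework is involved: networks are static
computational graphs over `H × W × C × N` arrays, with im2col + GEMM
convolutions (grouped and depthwise included) in C++ and hand-derived
backward passes for every op (convolution, batch norm with batch
statistics, ReLU/sigmoid/swish, max/average pooling, nearest upsampling,
concatenation, residual addition, squeeze-excitation gating). The backward
passes are validated against central finite differences, both per-kernel and
through a whole tiny network. Convolution padding is "same" with the extra
pixel on the bottom/right for stride-2 layers (the convention the original
backbones use); biases are disabled wherever BN directly follows.

A practical note on the sigmoid head: mathematically its outputs lie
strictly inside (0, 1), but in double precision a large logit saturates to
exactly 0 or 1. The strict-interior property is asserted on the tiny
network, whose logits stay moderate; the large presets assert the closed
interval.

**Flip equivariance.** `flip_equivariance_probe()` measures
`mean |unflip(f(flip x)) − f(x)|`. It is exactly 0 for a constant-output
network and finite for any network, but it is *not* near 0 for a random
convolutional network even on symmetric input: a convolution commutes with
horizontal flips only when its kernels are mirror-symmetric. What does hold
by construction — and is what TTA relies on — is that the TTA average
itself is flip-symmetric on symmetric input; the tests assert exactly these
three facts.

## Training

The loss is the sum of binary cross-entropy (probabilities clamped to
`[1e-7, 1 - 1e-7]` before logs) and soft Dice with smoothing 1 added to
numerator and denominator — the smoothing keeps empty-mask batches finite
and cancels exactly when prediction equals truth. The learning rate follows
a single half-cosine cycle stepped per epoch (the published schedules are
stated as epoch-level start/end values; whether the original schedule
restarted is unknowable from the text, so single-cycle is implemented and
the choice is recorded here). The four published recipes are presets
(`exp1`, `exp2`, `exp4`, `exp7`), asserted field-by-field in a
preset-integrity test.

"Stochastic weight averaging" is implemented as the element-wise mean of
the last *k* epoch checkpoints — terminal checkpoint averaging — because the
recipes pair SWA with a single monotone schedule rather than cyclic
restarts. Averaged weights leave batch-norm running statistics stale, so
`apply_swa()` refreshes them as the average of per-batch statistics over the
training data; without the refresh an averaged model with BN is not usable.

Training-loop IoU is computed on predictions binarized at 0.5, matching how
validation IoU is conventionally reported for this pipeline.

## Post-processing and ensembling

Probability maps are upscaled bilinearly to 1,024 × 1,024 **before**
thresholding by default, so the removal threshold counts native-resolution
pixels (1,024–4,096 px ≈ 0.1–0.4% of the frame); the alternative order
(binarize at model resolution, nearest-upscale the mask) is available via
`threshold_at = "model"` since the original resolution of the removal step
is unstated.

Binarization uses the strict boundary `P > B-TH` (a pixel exactly at the
threshold is background). Removal erases 8-connected components whose size
is not strictly larger than R-TH; a whole-mask mode (erase everything when
the total foreground is too small) is provided because the textual
description is ambiguous and that variant was common in competing solutions.
The search grid is 70 binarization values — 0.20 to 0.89 in steps of 0.01;
the stated count of 70 forces the exclusive upper bound — crossed with
{none, 1024, 2048, 3072, 4096}, i.e. 350 candidates, scored by macro mean
per-image IoU with the both-empty-equals-1 convention. Ties break toward the
least aggressive configuration: lowest B-TH, then no removal, then the
smallest R-TH, making the search fully deterministic.

Ensemble weights are normalized to sum to 1 before averaging: the published
best weights (40% EfficientNetB4-UNet, 40% SE-ResNeXt50-UNet, 20%
DenseNet169-UNet, 20% ResNet50-UNet) sum to 1.2, and an unnormalized
"average" would push probabilities above 1 and silently re-scale every
binarization threshold. Both that weighting and the 10/10/40/40 row that
tops the published validation grid are shipped as presets without
adjudicating which the final submission used.

## Metric conventions

Per-image IoU and Dice define the both-empty case as 1 (the Dice convention
is the competition's; we extend it to IoU so that threshold tuning does not
punish correct negatives — otherwise every all-negative validation image
would score 0 under any threshold and drag the search toward
over-segmentation). Pixel confusion rates are micro-pooled across images;
IoU/DSC/PSNR are macro-averaged — the two aggregation styles used in the
published per-model tables. Precision and recall return 0 on an empty
denominator. PSNR compares masks rescaled to {0, 255}; identical masks
return a configurable sentinel (default `Inf`), and callers that average
reports pass a finite cap.

## The synthetic phantom generator

The generator's role is to exercise code paths and enable
planted-parameter recovery, not radiographic realism. It emulates: grayscale
lung-field geometry (bright thorax ellipse, two dark lung ellipses, mild
illumination gradient, Gaussian pixel noise); thin crescent lesions hugging
the lung boundary, 1–3 components per positive image, with per-image
foreground fractions drawn from 0.005–0.08 (the thickness of each crescent
is found by bisection so the realized area hits its target); a 22% positive
prevalence matching the real corpus; and annotations written one RLE row per
component so the multi-row merge path is exercised. What it does **not**
emulate: rib and soft-tissue texture, acquisition metadata variety,
positioning variation, or the appearance continuum between subtle and
tension pneumothorax. Passing tests on phantoms therefore demonstrate
algorithmic correctness (codecs, geometry, optimization mechanics,
threshold recovery), not clinical performance.

Matched probability maps are `clip(blur(mask) + noise)`: with no blur and no
noise they reproduce the mask exactly at threshold 0.5, and increasing noise
strictly degrades mean IoU — the ordering the fixtures' tests verify.

## Problem sizes

The test-suite and acceptance computations run at desk scale by design:
phantom corpora of 6–30 images at 64–128 px, full-architecture forward
passes at 64 and 128 px, codec property suites over 500 random masks up to
1,024², and a 30-epoch overfitting run of the tiny preset (≈148 k
parameters) on eight 64-px images — sizes at which every computation is
exact, deterministic and reproducible on one CPU. The published headline
scores (e.g. mean test Dice of the full ensemble) require the competition
dataset, ImageNet-pretrained weights and GPU-scale training, and are out of
scope for the test suite; the tiny overfit run verifies that the training
machinery optimizes the intended objective, nothing more.

## Known limitations

* Pretrained ImageNet weights are accepted as an injection path
  (`save_network()` containers) but never downloaded; random initialization
  is the tested configuration.
* The DICOM reader is limited to uncompressed single-frame 8-bit
  explicit-VR-little-endian files; 12/16-bit windowing and multi-frame
  series are out of scope.
* SE-ResNeXt-101 and EfficientNet-B3 builders are provided for completeness
  but their published parameter counts are not asserted (the SE-ResNeXt-101
  figure is not reproducible from any standard weight layout we are aware
  of).
* Probability maps are stored as 16-bit quantized TIFF; values round-trip
  exactly at 1/65535 resolution.
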