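---
title: "Emulated Vedic arithmetic and the phantom segmentation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulated Vedic arithmetic and the phantom segmentation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vedicnn)
```

## What this package models

FPGA accelerators for convolutional networks replace the generic
multiply-accumulate units of a CPU/GPU with specialised arithmetic blocks.
One family of such blocks comes from Vedic mental-arithmetic sutras: the
*Urdhva Tiryagbhyam* (UT, "vertical and crosswise") rule forms all partial
product columns of a multiplication simultaneously; the *Nikhilam* rule
("all from 9 and the last from 10") multiplies numbers near a base via their
complements, extended by the *Anurupyena* ("proportionately") rule to scaled
working bases `m * B^k`; and a hybrid unit (CUTIN) decomposes an N-bit
product into four N/2-bit sub-products, routing each to the complement path
when its operands sit near a working base. Additions inside these units go
through a carry-save reduction and a final adder with clarified sum/carry
generation logic (CSCGL): a partial-sum unit (`s0 = a XOR b`, `c0 = a AND
b`), a carry unit that derives every selected carry combinationally from
`(s0, c0, cin)` with no multiplexer or duplicated conditional adders, and a
final-sum unit.

This package is a bit-accurate *software* emulation of that datapath, plus
the image-analysis pipeline that motivates it: IEEE-754 multiplication and
addition built on the integer units, convolution layers whose every scalar
multiply can be routed through the emulated arithmetic, a desk-scale
denoising CNN (DnCNN) for breast-lesion segmentation on synthetic
ultrasound-like phantoms, Pelican Optimization Algorithm (POA)
hyperparameter tuning, segmentation/image-quality metrics, and a
maximum-margin lesion classifier. Hardware synthesis, timing, area and
power are out of scope; the point is that every arithmetic claim can be
exercised and falsified on a desk.

## The arithmetic layer

Operands are fixed-width unsigned `bitvec` values. All units are verified
against machine integer arithmetic: exhaustively over all 65,536 8-bit
pairs, and on seeded samples at 16 and 32 bits (products above 53 bits
cross the R boundary as exact hex strings; tests compare them against an
independent 16-bit-limb long multiplication).

Numerical/design choices that the hardware description leaves open:

* **NAS-vs-UT dispatch inside CUTIN.** A sub-product of width `w` is routed
  to the complement path when both sub-operands lie within `2^(w-2)` of the
  nearest binary working base (`nas_shift = 2`, configurable). This
  preserves the complement method's "close to a base" applicability; the
  exact product is invariant to the dispatch, which the tests exploit.
* **Binary working bases.** The textbook illustrations of Nikhilam are
  decimal; the datapath is binary. Both modes exist. Decimal mode scans
  ratios `m` in 1..9 (matching the worked examples); binary mode scans
  `m` in {1, 3}, because with `m = 1` alone no scaled base exists between
  adjacent powers of two and the Anurupyena rule would be vacuous.
* **Tie-break.** When two working bases are equidistant from the operand
  pair, the smaller base wins (deterministic).
* **Carry-save convention.** The carry vector of a sum/carry pair is stored
  pre-shift; the weight-2 factor lives in the invariant
  `sum + 2 * carry = total`, keeping all rows the same width.
* **Recursion floor.** CUTIN recurses to 4-bit blocks, which are computed
  by direct UT column sums.

## Floating-point emulation

`fp_multiply` computes sign as XOR, exponent as the biased sum, and the
significand as a 24x24-bit (fp32) or 11x11-bit (fp16) product on the CUTIN
datapath, zero-extending operands to the unit's power-of-two width (32 and
16 bits respectively). If the product's leading bit is set, the mantissa
window starts one bit higher and the exponent is incremented; otherwise the
window starts at the next position and the exponent is unchanged. The
increment condition depends only on the product MSB: a published phrasing
that additionally requires the next 23 bits to be set is read as a
misstatement, since such a rule would mis-normalise almost all products.

Dropped low bits are **truncated by default** - the most literal reading of
"normalization eliminates the extra bit" for hardware - with
round-to-nearest-even available for reference comparison. Under RNE the
emulation is bit-identical to the host FPU on sampled normal operands; under
truncation it is within 1 ulp. `fp_add` aligns, adds significands through
the CSCGL unit with three guard bits and a sticky, normalises and rounds
the same way. Subnormals flush to signed zero on input and output
(the modelled exponent range covers normals only) and exponent overflow
saturates to the largest finite magnitude; both conditions are flagged.
Conformance sampling therefore draws exponents in ranges where products,
sums and partial cancellations stay normal (fp32: biased 90-160; fp16:
biased 13-18) - outside those ranges the flush/saturate policy, not the
rounding, dominates by design.

## Emulated convolution

`conv2d` computes each output pixel as the inner product of a patch vector
and a filter vector. The `exact` backend accumulates in host doubles. The
`cutin_fp32`/`cutin_fp16` backends convert both operands to the profile,
route every product through the emulated multiplier and accumulate over a
**balanced binary adder tree** of emulated additions - balanced because it
mirrors a hardware adder tree and makes the error analysable: operand
conversion and the truncated product cost at most 2 ulp per term, each of
the `ceil(log2(n))` tree levels at most 1 ulp of the accumulated magnitude,
giving the per-pixel bound implemented in `conv_ulp_bound()`
(`(depth + 4) * 2^-mbits * (|x| conv |w|) + n * min_normal`). Quantization
(`quantize`) is symmetric per-tensor with zero-point 0 and scale
`max|t| / (2^(bits-1) - 1)`; padding is zero-padding with "same" geometry
for odd kernels, which preserves spatial size through the network.

## The desk-scale DnCNN

The network is the canonical denoising stack: conv+ReLU, then conv+BN+ReLU
blocks, then a linear conv head (denoise, residual by default: the network
predicts the noise, which is subtracted from the input) or a 1-channel
sigmoid head (segment, thresholded to a binary mask). Published tables for
such accelerators sometimes list VGG-like 512-channel/4096-filter layers
with dropout and SoftMax; that architecture is inconsistent with a
denoising CNN, so the package implements the configurable conv/BN/ReLU
stack with desk-scale defaults (depth 3-9, width 8-32).

Training is **host arithmetic** (hand-written backprop, Adam, BLAS matrix
multiplies) - the hardware deploys inference, not training, so only
inference routes through the emulated backends, and batch
normalisation/activation stay in host floating point there too, as they do
on the device. Losses: MSE for denoising; Dice + binary cross-entropy for
segmentation (the field's standard compound loss; the evaluation fitness is
DSC/IoU, which is not differentiable as a hard mask). Everything is a pure
function of the training seed: the seed is set before weight
initialisation and drives shuffling, so identical seeds give identical
loss traces, and the segment masks under the emulated fp32 backend agree
with the exact backend on >= 99 % of pixels.

Morphological post-processing is a closing (dilation then erosion) with a
disc element - idempotent, fills pinholes, smooths lesion borders.

## Pelican Optimization Algorithm

POA is a population metaheuristic with two phases per iteration. The
published description names the phases and gives only the initialisation
equation `x_ij = l_j + rand * (u_j - l_j)`, so the canonical update rules
are adopted: exploration moves candidate `x` toward a prey `p` when the
prey's fitness is better (`x + rand * (p - I x)`, `I` randomly 1 or 2) and
away otherwise; exploitation perturbs `x + R (1 - t/T) (2 rand - 1) x`
with `R = 0.2` (configurable), the radius shrinking linearly to zero. Every
move is clamped to the bounds and accepted greedily, which makes the
best-so-far trace monotone by construction.

Two choices were genuinely open:

* **Prey selection.** The prey is a *randomly selected population member*
  (fitness already known), not a uniformly generated point. With a random
  point, greedy acceptance makes the exploration phase essentially inert
  once the population is better than a typical random draw, and the sphere
  benchmark (m = 5, N = 20, T = 100) stalls around 1e-1; with a random
  member it reaches ~1e-18, consistent with the deep convergence this
  algorithm family reports. The selected-member reading is therefore
  adopted.
* **Warm start.** For hyperparameter tuning the initial population includes
  the incumbent default configuration. This is standard practice when a
  working configuration exists, and with greedy acceptance it guarantees
  the tuned result is never worse than the default.

The tuning fitness trains a short-budget segment-head DnCNN per candidate
and returns `1 - (0.5 DSC + 0.5 IoU)` on a validation split; the DSC/IoU
weights are configurable (equal weighting is the neutral choice). The
search space is log10 learning rate [-4, -1], depth {3..9}, width {8..32},
mask threshold [0.2, 0.8], post-processing radius {0..3}.

Short-budget fitness is an imperfect proxy for full-budget quality (a
learning rate that shines over 10 epochs can underperform over 150), so
deployment uses incumbent-vs-challenger validation (`select_segmenter`):
the POA winner and the default configuration are both re-trained at the
full budget and the model with the better DSC/IoU fitness on the held-out
validation phantoms is deployed. The test set plays no role in either
stage of the selection.

## The phantom generator

Real breast-ultrasound collections (B-mode images with expert lesion masks
and benign/malignant labels) cannot be redistributed here, so the package
generates seeded phantoms that emulate their statistical structure:

* background tissue: a smooth random field around intensity 0.55;
* **benign** lesions: hypoechoic (darker by the configured contrast,
  default 0.3) ellipses, aspect ratio 0.65-0.95, low-amplitude (0.03)
  low-harmonic boundary perturbation, well-defined margin (~1 px blend);
* **malignant** lesions: high-amplitude (0.22) harmonics 5-9 -
  spiculation - plus a diffuse margin (~3 px) and heterogeneous interior
  texture;
* noise: multiplicative speckle `x * (1 + s (R / E[R] - 1))` with `R`
  Rayleigh - the standard first-order ultrasound speckle model - at
  `s = 0.3`, plus additive Gaussian noise (sigma 0.02).

Lesion area tracks the requested fraction (default 8 % of the image)
within +/-20 %; masks are exact (the soft margin affects only intensities).
The boundary-roughness statistic (variance of the circular second
difference of the normalised radius-angle profile) separates the classes
with probability >= 0.95, which is what makes the downstream classifier
property testable. The generator does *not* model attenuation, shadowing,
posterior enhancement, probe artefacts, or inter-observer mask variability
- passing tests demonstrate the pipeline's mechanics and the arithmetic
claims, not clinical performance.

Default image size is 128 x 128; the training experiments in the test
suite and the acceptance script run at 32 x 32 with 40 training and 60
test phantoms, a denoiser of depth 5/width 16 (60 epochs) and a segmenter
of depth 5/width 16 (150 epochs), sizes at which a full end-to-end run
completes in minutes on one core while still clearing +3 dB denoising PSNR
and 0.85 mean DSC. The stratified 80:20 split helper rounds per class
(312 phantoms split 250/62).

## Metrics

Pixel-level confusion counts feed accuracy, precision, specificity,
sensitivity, F-score, IoU and Dice; zero denominators yield flagged `NA`s
rather than zeros or errors, so empty-mask edge cases are visible. Dice
and IoU obey `DSC = 2 IoU / (1 + IoU)` identically. Lesion-level confusion
counting appears only in the classifier stage. PSNR is `10 log10(peak^2 /
MSE)` with an `Inf` sentinel for identical images. SSIM uses the standard
11 x 11 Gaussian window (sigma 1.5), stabilisers `(0.01 peak)^2` and
`(0.03 peak)^2`, weighted population moments, and averages over fully
interior window placements; the test suite checks it to 1e-6 against an
independent direct per-window implementation.

## The classifier

"P-SVM" is implemented as a linear maximum-margin separator (soft-margin
SVM, cost 1) on standardised handcrafted features - area fraction,
circularity `4 pi A / P^2` (with a half-pixel contour-offset perimeter
correction, so a rasterised disk scores within 0.05 of 1), solidity,
boundary curvature variance, interior variance, local contrast, interior
mean, and interior/background contrast ratio - computed on the largest
connected component. The kernel is configurable; a hyperplane separator is
the faithful reading of the described decision rule, and the decision
score is hard 0/1 (benign/malignant) with the signed margin reported for
diagnostics.

In the pipeline the classifier sees the *same* feature distribution at
training and prediction time: features are computed on predicted,
post-processed masks on both sides (ground-truth masks as fallback for
empty predictions). With ground-truth masks at the generator's default
128 x 128 resolution the classes separate essentially perfectly; at the
32 x 32 desk scale, segmentation and closing smooth away much of the
spiculation signal that distinguishes malignant boundaries, and
end-to-end classification accuracy drops accordingly - a resolution
limitation of the desk-scale protocol, not of the feature set.

## Reproducibility and limitations

One seed drives everything: phantom generation, weight initialisation,
shuffling, the optimizer, and the pipeline report embeds the configuration
hash and seed and contains no timestamps, so a fixed configuration
reproduces it bit-identically. Known limitations: training at 32 x 32
limits boundary fidelity for the most spiculated lesions (per-image DSC
can dip to ~0.7 while the mean clears 0.85); the emulated backends are
orders of magnitude slower than host arithmetic (they exist for
verification, not speed); fp16 emulation flushes subnormals, so deep
cancellation differs from a subnormal-preserving reference; and the
phantoms are statistical stand-ins, not anatomy.
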