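---
title: "Methods: the SCAT-inception classifier and its evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SCAT-inception classifier and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Glioblastoma (GBM) and solitary brain metastasis (MET) look deceptively
similar on contrast-enhanced T1-weighted (ceT1W) MRI — both present as an
enhancing lesion with surrounding edema — yet their treatments differ
fundamentally. scatnet implements a convolutional classifier for this
two-class problem on 2-D lesion slices, together with everything needed to
evaluate it honestly: region dataset construction, augmentation, case-level
cross-validation and diagnostic metrics. GBM is the positive class
throughout.

Because clinical ceT1W cohorts are private, the package ships a synthetic
lesion-phantom generator as a first-class, tested module. It exists to make
the pipeline falsifiable at desk scale, not to claim clinical performance.

## The model

The classifier is an inception-style network. An inception unit runs several
parallel convolution branches with different kernel shapes (1x1, 1x3, 3x1,
3x3, 5x5, and a pooled branch; five branches in the A/B/C variants) over
the same feature map and concatenates their outputs along the channel axis,
capturing structure at several receptive-field sizes at once.

The distinctive ingredient is the spatial convolutional attention operator
(SCAT). Given a feature map $x \in \mathbb{R}^{C \times H \times W}$:

1. a 1x1 convolution reduces $C$ channels to $\max(1, C/r)$ (reduction
   ratio $r = 4$ by default),
2. a second 1x1 convolution maps the reduced stack to attention logits
   $\ell$,
3. a softmax over the $H \times W$ positions turns $\ell$ into a spatial
   distribution $a$ with $\sum_{h,w} a_{hw} = 1$,
4. the feature map is reweighted elementwise: $y = x \odot (HW \cdot a)$.

The $HW$ rescaling makes *uniform* attention the exact identity; without
it, the softmax would shrink every activation by $1/(HW)$ and couple
attention to image size. The network stacks 3 SCAT-A, 2 SCAT-B, 4 C, 1 D
(stride-2 grid reduction) and 1 E unit — 11 inception units — followed by
global average pooling, dropout (rate 0.5) and a linear head with 2 logits.

## Design choices the architecture description leaves open

These points are genuine gaps in the source description; the package makes
an explicit choice for each and exposes it in configuration:

* **Softmax axis.** The attention could normalize across space or across
  channels. Spatial normalization is the default — it is what "pixel-level
  attention" and the operator's name imply — and `attn_axis = "channel"`
  provides the channel variant for ablation.
* **Attention channels.** One spatial attention map is broadcast over all
  feature channels (configurable). The alternative (one map per channel)
  multiplies parameters for no demonstrated benefit at these widths.
* **Internal composition of C/D/E units and the stem.** Unspecified
  upstream; we follow the inception-v3 conventions the variant letters
  evoke: C uses asymmetric 1x3/3x1 factorized branches, D is the stride-2
  reduction block (with a pooled pass-through branch), E the widened
  filter bank. The stem is two stride-2 3x3 convolutions plus a stride-2
  max-pool, reducing resolution 8-fold before the first unit.
* **Branch widths.** Each branch defaults to `floor(in_channels / 4)`
  channels (minimum 1), overridable per block; `width_multiplier` scales
  the whole network for desk-scale testing.
* **Normalization and initialization (non-paper engineering).** Every
  branch convolution is followed by batch normalization, the
  inception-family practice. This is load-bearing: an 11-unit stack of
  thin unnormalized branches reliably stalls at the $\ln 2$ plateau under
  Adam at the reference learning rate. Likewise the attention-logit
  convolution is zero-initialized, so every SCAT operator starts as the
  identity; with random logits the $HW$-rescaled softmax amplified
  activations by two orders of magnitude at initialization. Weights are
  otherwise Kaiming-uniform from a recorded seed. The SCAT convolutions
  themselves are not normalized — normalizing logits before a softmax
  would fight the attention mechanism.
* **Loss and schedule.** Softmax cross-entropy, constant learning rate,
  final-epoch weights (no early stopping or checkpoint selection). The
  reference hyperparameters are Adam at 0.01 for 250 epochs, dropout 0.5,
  batch size 16 (batch size is our choice; the source states none).

## The synthetic cohort: what it emulates, what it does not

`generate_case()` draws, per case, a lesion center (off-center with
jitter), a core radius, and a low-order harmonic perturbation of the
boundary radius, then renders three adjacent-slice variants with nested
masks: the *core* (lesion interior) and the *edema* halo (an annulus out
to `edema_halo_ratio` times the core boundary). Default phenotypes encode
the radiological contrast that matters for this task:

| parameter | GBM | MET | meaning |
|---|---|---|---|
| `core_radius_range` | 10–18 px | 8–14 px | mean core radius |
| `rim_intensity` | 0.85 | 0.85 | enhancing rim brightness |
| `center_intensity` | 0.25 | 0.85 | lesion center (necrosis vs homogeneous) |
| `boundary_irregularity` | 0.25 | 0.02 | harmonic radius perturbation |
| `edema_halo_ratio` | 1.8 | 1.6 | edema extent / core radius |
| `noise_sd` | 0.02 | 0.02 | additive Gaussian noise |

Intensities are fractions of the display range; a per-case gain jitter
(±5%) emulates acquisition variation, and a 3x3 box blur softens mask
edges. With `noise_sd = 0` the classes are separable by a single
rim-to-center intensity ratio threshold (`ring_ratio_predict()`), which is
asserted in the tests: the end-to-end training check therefore certifies
that the pipeline can extract an attainable signal — it does **not**
certify clinical performance. Real lesions differ in texture, anatomy,
partial-volume effects and class overlap; no conclusion about the 92.3%
clinical accuracy can be drawn from green synthetic tests.

## Preprocessing and augmentation

For each case and region (`core`, `edema`, or `overall` = core + edema)
the slice is cropped to the region-mask bounding box (2 px margin),
expanded to a square window, resized bilinearly to the network input size
and min-max normalized to [0, 1]; the per-image mean is recorded and
subtracted at batch assembly (data centering). Augmentation multiplies the
corpus by `factor` (default 3: each original is kept and gets two
variants) with seeded random rotation (±15°), integer translation (±8 px)
and linear contrast jitter (0.8–1.2) around the image mean — grayscale
contrast jitter standing in for "color contrast" transforms on
single-channel MRI. Augmentation is applied to training folds only; the
ranges keep ≥90% of lesion pixels in frame, which the tests assert.

## Evaluation protocol

Splitting is always at case level: the three slices of a patient move
together, and every pipeline entry point audits train/eval case overlap
and fails hard on leakage. `make_folds()` deals shuffled cases round-robin
within class (offset carried across classes), so 251 cases give fold sizes
{51, 50, 50, 50, 50} with per-fold class counts within one case of
proportional. A fixed-count stratified split (`split_fixed()`) mirrors a
207/44-style partition; both modes exist because the source protocol
describes both and they are not mutually consistent.

Metrics follow the standard confusion-matrix definitions with GBM
positive: accuracy $(TP+TN)/n$, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$. A metric whose denominator is zero is reported as `NA` with
a warning, never silently as 0. AUC is the Mann–Whitney pair statistic
(ties at ½), hence invariant under monotone score transforms. Slice
probabilities are fused per case by majority vote of thresholded slices
(odd slice count: no ties), and both slice- and case-level metrics are
reported, since the granularity of the reference numbers is unstated.
Fold aggregation uses the arithmetic mean and *population* variance
(denominator $n$), with rounding to one decimal only at display.

## Numerical notes

* Convolutions are im2col + BLAS matrix products (RcppArmadillo); the
  backward pass was verified against central finite differences through
  the full network. A caveat for anyone repeating that exercise: with
  zero-initialized biases, many pre-ReLU activations are *exactly* zero
  and finite differences straddle the kink; perturb parameters off zero
  before comparing.
* Same-padding everywhere (`floor(k/2)` per axis); stride-2 layers halve
  odd extents with ceiling division, and the `D` unit halves spatial
  dimensions.
* Average pooling counts padded cells in the divisor (`k²`), keeping its
  backward pass a constant fan-out.
* Batch-norm running statistics live outside the parameter tree and are
  reset at the start of every training run, so a run is a pure function
  of (data, configuration, seed).
* NIfTI-1 I/O is implemented minimally in R (no NIfTI package exists in
  the supported stack) and was cross-checked against nibabel; images
  round-trip within float32 quantization.

## Scaled-down acceptance check

The end-to-end test trains the reference architecture at
`width_multiplier = 0.25` on 64x64 crops of 40 low-noise synthetic cases
with 5-fold CV for 30 epochs. The pass threshold — mean case-level
accuracy ≥ 0.90 — was frozen after a three-seed pilot (0.90, 1.00, 1.00)
before being added to the suite, and the test also asserts that the
training loss decreases in every fold. Runtime is a few minutes on one
CPU core.

## Known limitations

* 2-D single-modality slices only; no volumetric context or multimodal
  fusion.
* The synthetic phantoms are geometric idealizations; texture-level
  radiomics are absent by construction.
* Baseline architectures (VGG/UNet/GoogLeNet) are out of scope; the SCAT
  ablation hook (`attn_weights = 0` gives the identity) is the supported
  comparison.
* Training is CPU-bound R/C++; the reference 250-epoch protocol on a
  full-width network is feasible but slow — the configuration system
  exists precisely so that scaled studies are explicit and reproducible.
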