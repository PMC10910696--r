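---
title: "Attention-aware joint optic disc and cup segmentation: methods and design"
author: "odcseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-aware joint optic disc and cup segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glaucoma screening from retinal fundus photographs rests on the vertical
cup-to-disc ratio (CDR): the optic cup's vertical diameter divided by the
optic disc's. A normal CDR sits around 0.3–0.4; larger values indicate risk.
Computing CDR automatically requires segmenting both structures, which is
hard because the cup boundary is a soft luminance transition inside the
disc, vessels cross and occlude both boundaries, and labeled medical data
are scarce.

`odcseg` implements a one-stage attention-aware encoder–decoder for joint
disc/cup segmentation, a rim-constrained multi-label training loss, an
optional contrastive self-supervised pretraining stage for the encoder, the
evaluation metrics used in this literature (F1, Dice, boundary localization
error, CDR), and a synthetic fundus generator so that the entire pipeline is
exercised end-to-end without any external data.

## Network

The encoder is a residual CNN pyramid producing feature maps $F_1..F_4$ at
strides 4, 8, 16 and 32. After each stage the feature map is flattened into
tokens $X \in \mathbb{R}^{C \times P}$ (position $p = n\,h\,w + r\,w + c$,
row-major) and passed through a **multi-scale attention block**:

$$X' = \mathrm{MHSA}(\mathrm{LN}(X)) + X, \qquad
  X'' = \mathrm{MSMLP}(\mathrm{LN}(X')) + X'.$$

MHSA is standard pre-norm multi-head self-attention. MSMLP replaces the
transformer MLP with a KNN mixer: token similarity is the Gram matrix
$S = \tilde F^\top \tilde F$ of L2-normalized channel features (the
$\ell_2$-distance ranking with the constant removed), each query gathers its
top-$k$ most similar tokens for $k \in \{4, 6, 8\}$, a two-layer 1×1
convolution $\varphi$ (ReLU between) transforms each neighbor, a max is
taken over the neighbor axis, and the three scale outputs are summed.
Neighbor selection is a ranking and carries no gradient; gradients flow
through the gathered values.

After stage 4 an **aggregation attention block** clusters the (normalized)
tokens into $C{=}3$ groups with seeded k-means — intended to separate disc,
cup and background token populations — then runs single-head scaled
dot-product attention ($\mathrm{SoftMax}(QK^\top/\sqrt{D})\,V$ with
$Q = W_Q X + B_Q$ etc.) separately over each group's tokens and over the
3-centroid sequence, and adds each updated centroid back to its members.

The decoder upsamples bilinearly (×2 per stage), concatenates the matching
encoder skip, applies two 3×3 convolutions with GroupNorm/ReLU, and ends in
a 1×1 convolution with two independent sigmoid channels (multi-label: one
binary classifier per structure). Cup ⊆ disc is **not** enforced
architecturally; the constraint enters only through the loss, and
`predictMasks(..., clip_cup = TRUE)` offers clipping as an opt-in
post-process.

## Losses

**Rim-constrained multi-label loss.** With per-pixel probabilities
$p_D, p_C$ and binary truths $g_D, g_C$ (and rim truth $g_R = g_D - g_C$):

$$\mathcal{L} = \tfrac13\big(\mathrm{BCE}(p_D, g_D) + \mathrm{BCE}(p_C, g_C)
 + \mathrm{BCE}(\mathrm{clamp}(p_D - p_C,\ \varepsilon,\ 1-\varepsilon),\ g_R)\big).$$

Two deliberate numerical choices: (i) the loss is the standard negative
log-likelihood, minimized — the cross-entropy sign convention; (ii) the rim
"probability" $p_D - p_C$ can be non-positive when the network predicts cup
mass outside the disc, where a bare logarithm would be undefined, so the
difference is clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$. Clamping keeps the loss finite while preserving the
gradient direction of the constraint; a sigmoid-of-logit-difference variant
was considered and rejected as it changes the loss scale of the rim term
relative to the other two. Pixel aggregation is a plain mean, making the
loss scale resolution-independent.

**InfoNCE.** $L = -\log \frac{\exp(q\cdot k_+/\tau)}{\sum_{i=0}^{K}
\exp(q\cdot k_i/\tau)}$ over one positive and $K$ negatives, $\tau = 0.07$
by default. Negatives are in-batch: with batch size $B = 8$, each anchor's
negatives are the $2(B-1) = 14$ other augmented views, so the uniform-
similarity baseline is $\ln 15 \approx 2.708$. No momentum queue is used;
both branches share weights (siamese).

## Self-supervised pretraining

Each image yields two views through, in order: a uniformly chosen rotation
from {0°, 90°, 180°, 270°}, kernel sharpening alpha-blended with the input
($\alpha \sim U[0,1]$), gamma contrast ($\gamma \sim U[0.5, 2]$), and
Gaussian blur ($\sigma \sim U[0, 0.5]$). The augmentation order is fixed for
reproducibility; each stage clips to $[0,1]$. The deepest encoder map is
pooled by RoiAlign with the full-image box to a fixed 24×24 grid (bilinear,
sampling ratio 2), flattened, projected by a single fully connected layer to
a 128-dimensional embedding and L2-normalized; pooling to a fixed grid keeps
the head size independent of image resolution. The head pools $F_4$ only.
Pretraining defaults: 30 epochs, Adam at 1e-4 decayed ×0.1 every 15 epochs,
batch 8. `transferWeights()` copies every encoder-side tensor (stem,
residual stages, both attention blocks) into a segmentation model and
reports transferred/skipped names.

## Metrics

F1 ($2PR/(P{+}R)$) and Dice ($2\,TP/(2\,TP{+}FP{+}FN)$) coincide for binary
masks; the package computes both and tests the identity. Empty-mask
convention: both masks empty → 1, exactly one empty → 0.

**Boundary localization error** samples both contours along $N = 24$ rays at
15° spacing from the ground-truth disc centroid (0.25-px ray marching,
radius = outermost mask pixel on the ray) and reports the mean absolute
radial difference $\frac1N \sum_\theta |d_g^\theta - d_0^\theta|$. A
difference-of-squares radicand $\sqrt{d_g^2 - d_0^2}$ appears in parts of
this literature but is not a distance (negative radicand whenever the
prediction overshoots); `bleError(..., strict_formula = TRUE)` evaluates it
literally (NaN on overshoot) for auditability, and the absolute-difference
form is the default. Both contours of a structure use the same center so the
radii are comparable.

**CDR** is the ratio of vertical extents (max row − min row + 1) of cup and
disc masks.

## Synthetic data

`makeSample()` renders a bright elliptical disc containing a brighter
elliptical cup (background < disc < cup in the green channel, matching real
fundus contrast ordering) on a textured red-orange background, with
quadratic-Bézier dark vessel distractors, a slight blur for soft anatomy
edges, and additive Gaussian noise (sd 0.02). Masks are exact ellipse
rasterizations of the pre-blur geometry, so cup ⊆ disc holds by
construction and is additionally rejected-checked analytically (256 cup
boundary points against the disc inequality). Pixel centers sit at integer
(row, col) coordinates, 0-based. Default canvas 128×128 (up to 512
supported); default cup scale 0.4 reflects the upper normal CDR.
`randomSceneParams()` jitters center, axes, rotation, cup scale/offset and
vessel count within ranges that keep the geometry valid.

What the generator does **not** emulate: photographic vignetting and color
balance variation, pathology (hemorrhages, exudates, peripapillary
atrophy), annotation ambiguity at the soft cup border, and camera-specific
resolution/noise statistics. Passing tests on synthetic data therefore
demonstrate that the architecture, losses, optimization and metrics are
implemented correctly and can learn this geometry — not clinical-grade
accuracy on real fundus photographs.

## Numerical and design choices

- **Self-inclusion in top-K.** The cosine diagonal is maximal, so each
  query's neighbor set contains itself; $k = 1$ reduces to a per-token MLP.
  Ties break toward the lower index (deterministic across platforms).
- **Zero-initialized residual branches.** The MHSA output projection, the
  second $\varphi$ layer and the aggregation value projection start at zero,
  so every attention block begins as an identity (or input + centroid).
  This gives exact reduction identities for testing and a stable start.
- **Per-scale $\varphi$ weights.** Each neighbor scale has its own two-layer
  MLP; fusion is unweighted addition.
- **Shared Q/K/V** between member and centroid attention in the aggregation
  block; centroids are means of the L2-normalized member tokens (the
  k-means space) and are recomputed differentiably from the final
  assignment.
- **k-means**: k-means++ initialization, ≤10 Lloyd iterations over the full
  token set (the token count at stride 32 is small, so the mini-batch is
  the whole set), empty clusters repaired by re-seeding the centroid at the
  farthest point; identical degenerate inputs terminate with all tokens in
  one cluster. The assignment is seeded by the model seed, making forward
  passes deterministic.
- **Normalization**: GroupNorm (4 groups) throughout — supervised training
  uses batch size 1, where batch statistics degenerate; `norm = "instance"`
  restores the batch-norm-at-batch-1 behaviour (per-channel statistics).
- **Softmax stability**: scores are shifted by the global max before
  exponentiation; attention score magnitudes make per-row shifts
  unnecessary.
- **Neighbor scales at coarse stages** are clipped to the token count
  (stride 32 on a 128 px input has 16 tokens).
- **Head count**: 4 by default; the `shallow` preset uses 2 so the per-head
  dimension stays at 6 with 12 channels at stage 1.
- Encoder input sizes must be divisible by 32; `predictToFile()` resizes
  arbitrary inputs to the nearest multiple and inverts the transform on the
  probability maps before thresholding.

## Scaled-down study sizes

CPU-scale runs used by the tests and the acceptance script: 40 training and
10 held-out synthetic 128×128 images, 200 optimizer steps with the
`shallow` preset (stage widths 12/24/48/96, one residual block per stage,
~444k parameters), and 16 unlabeled images for 3 pretraining epochs. The
preset width was chosen so that the cup — a minority structure whose
features emerge noticeably later than the disc's — trains reliably across
initialization seeds within the reduced step budget; at half these widths
the cup channel stays suppressed past 400 steps for some seeds (the early
rim-term pressure and the small cup pixel fraction both slow it down). The
full-scale recipes keep the reference schedules (supervised: 100 epochs,
Adam 1e-4, ×0.1 every 50 epochs, batch 1; pretraining: 30 epochs, 1e-4,
×0.1 every 15, batch 8). The 200-step runs use Adam at 1e-3: they cover
roughly 5% of the full schedule, and the learning rate is scaled up
accordingly for the reduced budget — a choice made for the scaled runs as
such, not a tuned value. Validation splitting for checkpoint selection
defaults to a seeded 80/20 split of the training manifest.

## Known limitations

- The autodiff engine is define-by-run with dense R arrays; it is adequate
  for the shallow preset on CPU but not for GPU-scale training.
- No ROI cropping stage, deep supervision, ellipse fitting or polar
  transforms (deliberate non-goals; the network is one-stage).
- The aggregation block's three clusters are a heuristic for disc/cup/
  background token populations; nothing enforces that semantic alignment.
- Checkpoints are RDS archives with a format-version string; they are
  runtime artifacts, not an interchange format.
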