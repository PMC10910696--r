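# odcseg — attention-aware joint optic disc and cup segmentation

Glaucoma screening from fundus photographs hinges on the **vertical
cup-to-disc ratio (CDR)**: the optic cup's vertical diameter over the optic
disc's. Values above roughly 0.4 indicate risk, and computing CDR
automatically requires segmenting both structures — difficult because the
cup boundary is a soft luminance transition, vessels occlude both contours,
and labeled medical images are scarce.

`odcseg` is an R package for researchers in retinal image analysis that
implements a one-stage attention-aware pyramid encoder–decoder for joint
disc/cup segmentation, together with everything needed to train and
evaluate it end-to-end on CPU:

- **Multi-scale KNN attention**: after each encoder stage, tokens pass a
  pre-norm block `X' = MHSA(LN(X)) + X; X'' = MSMLP(LN(X')) + X'`, where
  MSMLP gathers each token's top-k most similar tokens (cosine of
  normalized channel features, k ∈ {4, 6, 8}), transforms neighbors with a
  two-layer 1×1-conv MLP, max-reduces over neighbors and sums the scales.
- **Aggregation attention**: tokens of the deepest stage are clustered into
  3 groups by seeded k-means (disc / cup / background populations);
  scaled dot-product attention `SoftMax(QKᵀ/√D)V` runs separately within
  each group and over the 3-centroid sequence, and updated centroids are
  broadcast back onto their members.
- **Rim-constrained multi-label loss**:
  `L = (BCE(p_D, g_D) + BCE(p_C, g_C) + BCE(clamp(p_D − p_C), g_D − g_C)) / 3`,
  injecting the prior that disc minus cup is the neuroretinal rim.
- **Contrastive self-supervised pretraining** (InfoNCE, τ = 0.07, in-batch
  negatives, siamese encoder; rotation/sharpen/gamma/blur augmentations;
  full-image RoiAlign to 24×24 before the projection head) to initialize
  the encoder from unlabeled images.
- **Metrics**: pixel F1 and Dice, boundary localization error (mean
  absolute radial gap over 24 rays from the disc centroid), and CDR.
- **Synthetic fundus generator**: reproducible nested-ellipse scenes with
  vessel-like distractors so that the full pipeline trains and evaluates
  with no external data.

The network and its training loop run on a compact reverse-mode autodiff
engine included in the package (dense R arrays + a few compiled kernels);
no deep-learning framework is required.

## Worked example

Generate data, train briefly, and evaluate:

```r
library(odcseg)

train   <- lapply(1:40, function(i) makeSample(randomSceneParams(1000 + i)))
heldout <- lapply(1:10, function(i) makeSample(randomSceneParams(9000 + i)))

fit <- trainModel(train,
                  trainConfig(epochs = 10, lr = 1e-3, seed = 1, val_frac = 0),
                  steps = 200)        # shallow preset, 128x128 images
report <- evaluateModel(fit$model, heldout)
report[report$id == "mean",
       c("disc_f1", "cup_f1", "disc_ble", "cup_ble", "cdr_pred", "cdr_gt")]
```

Output from this exact run:

```
   disc_f1    cup_f1  disc_ble  cup_ble  cdr_pred    cdr_gt
 0.9797476 0.8536278 0.4677083 1.666667 0.3997247 0.4165105
```

After 200 optimizer steps the disc is segmented nearly perfectly (F1 0.98,
mean boundary error under half a pixel); the cup — a low-contrast structure
inside the disc — reaches F1 0.85 with a boundary error of ~1.7 px, and the
predicted mean CDR (0.40) tracks the ground-truth mean (0.42). Longer
schedules (the default `trainConfig()` is 100 epochs) close the remaining
gap.

Single functions are usable on their own, e.g.

```r
rimLoss(0.8, 0.3, 1, 0)          # 0.4243 = -(ln .8 + ln .7 + ln .5)/3
cupDiscRatio(disc_mask, cup_mask)
```

A command-line front end with `synth` / `pretrain` / `train` / `eval` /
`predict` verbs is installed at `inst/cli/odcseg.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/odcseg.R", package="odcseg"))') \
    synth --n 40 --split train --seed 1 --out data/train
```

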