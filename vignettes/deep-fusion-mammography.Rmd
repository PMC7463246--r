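---
title: "Deep fusion learning for mammographic ROI classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep fusion learning for mammographic ROI classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mammographic computer-aided diagnosis must find small abnormalities
(calcifications, circumscribed or spiculated masses) in large, noisy,
low-contrast films. With only a few hundred annotated regions of interest
(ROIs) per archive, training a deep network end-to-end overfits badly.
`mammofuse` implements a two-stage remedy:

1. decompose each 120 × 120 ROI into many random 72 × 72 patches, turning
   hundreds of ROIs into hundreds of thousands of training items;
2. classify patches with a small trainable *fusion head* over a frozen
   convolutional backbone, then aggregate the per-patch labels of each ROI
   by majority voting,

$$\hat{y}_i = \operatorname{mode}\{\,l_1(x_i),\dots,l_n(x_i)\,\},
\qquad n = 25,$$

where $l_j(x_i)$ is the predicted label of the $j$-th patch sampled from
ROI $x_i$. Voting suppresses patch-level noise: the ROI is misclassified
only if more than half of its patches are.

Two heads are provided over the five pooled block outputs (branches
L1–L5) of a VGG-style backbone:

* **fusion1** — global average pooling (GAP) of each selected branch,
  concatenated. The fused width is the sum of the block channel counts
  (1472 for VGG16 branches 1–5).
* **fusion2** — per branch: batch normalization → 2 × 2 stride-2 average
  pooling → 1 × 1 convolution to a channel bottleneck (ReLU) → GAP. The
  1 × 1 convolution mixes channels at each location (cross-channel
  fusion) and shrinks the fused width to
  `length(branches) * bottleneck_channels`.

Either way the concatenated vector passes through BN → FC1 (ReLU) → FC2
(ReLU) → softmax. Only the branch/head parameters train; the backbone
convolutions are frozen — this is the central contract, tested bit-exactly.

### Assumptions

* Benign and malignant abnormalities are pooled into one *Tumor* class;
  the discriminative target is Normal vs Tumor tissue texture.
* Patches inherit their ROI's label. This is deliberately noisy — a patch
  from an abnormal ROI may contain little of the lesion — and is exactly
  the noise the voting stage is designed to absorb. It works because every
  72 × 72 patch of a 120 × 120 ROI covers the ROI's central 24 × 24 block,
  where the annotated abnormality is centred.
* Patch-wise centralization (subtracting each patch's own mean) removes
  absolute brightness, so the head must discriminate on structure and
  local contrast, not exposure.

## Pipeline parameters

| stage | parameter | default | notes |
|---|---|---|---|
| denoising | median kernel | 3 × 3 px | impulse-noise removal; reflected borders |
| enhancement | CLAHE clip limit | 2.0 | × the uniform bin height, per 256-bin tile histogram |
| enhancement | CLAHE tile grid | 8 × 8 | tiles padded by reflection; bilinear LUT interpolation |
| breast mask | threshold | 15 | intensity units; then disk-5 closing, largest component |
| ROI | half side | 60 px | window side 120; covers most annotated radii |
| ROI | dark-crop rule | >95% of a row/col ≤ 10 | trims non-breast bands before rescaling |
| patches | size | 72 px | offsets uniform on {0..48}², with replacement |
| patches | per-ROI counts | 500 normal / 2000 abnormal | desk-scale runs use 50/200 (1/10) |
| split | fractions | 60/20/20 | stratified by label, at ROI level |
| training | optimizer | Adam, lr 1e-3, batch 64 | cross-entropy; optional inverse-frequency class weights |
| training | epochs / patience | 20 / 5 | early stopping on validation loss |
| voting | n | 25 | fresh patches per test ROI, centralized, never augmented |

The preprocessing constants (median 3 × 3, CLAHE 2.0/8 × 8) are the
conventional values used across mammography preprocessing pipelines, and
every one of them is exposed as an argument.

## Design choices where the design was open

**Branch taps and unstated widths.** Branches tap each block's max-pool
output. FC widths (256/128), the fusion2 average-pool geometry
(2 × 2 stride 2) and the bottleneck width (64) have no canonical values in
the literature; they are package defaults, all configurable in
`fusion_spec()`.

**Window clamping.** An ROI window that would overrun the image is shifted
inside (never zero-padded), keeping ROI content on real imagery. The
annotated circle still lies inside the clamped window for any radius ≤ 60.

**Coordinate origin.** MIAS annotates centers bottom-left; matrix indexing
is top-left, so `annotation_to_rowcol()` flips the y axis. Without the
flip, extracted ROIs miss their lesions.

**Voting details.** Voting patches are freshly sampled per test ROI under
the evaluation seed (`n = 25`). The tie rule prefers Tumor — with odd `n`
binary ties cannot occur, but the rule exists for even `n` and favours
recall, the clinical priority. The ROC/PR score is the mean Tumor softmax
probability over the same patches; the vote fraction is available as an
alternative.

**Checkpoint selection.** Early stopping watches validation loss (patience
5), but the returned checkpoint is the epoch with the best validation
*accuracy* (ties broken by loss). Validation loss routinely rises from
over-confidence while accuracy still improves, and accuracy is what the
voting stage consumes.

**Augmentation timing.** Augmentation (horizontal/vertical flips and 90°
rotations, each with probability 0.5 — isometries that preserve lesion
statistics and the zero patch mean) is applied once when the training
patch set is assembled, not per epoch. With a frozen backbone the package
trains on cached backbone activations, and per-epoch augmentation would
force a full backbone re-forward every epoch for no statistical benefit at
desk scale. Conceptually the adjusted (centralized, augmented) patch set
exists before training starts; training then iterates over it.

## Numerical choices

**Cached-activation training is exact.** Because the backbone never
trains, each patch's branch activations are computed once. For fusion2 the
branch BN uses minibatch statistics over the *pre-pool* feature maps;
these are recovered exactly from cached per-patch channel sums and sums of
squares, and since a per-channel affine commutes with spatial average
pooling, applying the BN affine to the cached *post-pool* maps gives
bit-equal results to BN-then-pool. Gradients are exact too: the frozen
input makes the BN batch statistics constants of the optimization, so the
branch BN backward reduces to an affine backward. The head BN (whose input
depends on trainable parameters in fusion2) uses the full batch-norm
backward pass.

* BN: biased variance, ε = 1e-5, running statistics with momentum 0.1
  (used at inference, making prediction deterministic).
* Initialisation: uniform fan-in scaling (`U(±1/√fan_in)`) for head
  weights, `U(±√(6/fan_in))` for backbone convolutions, under the run
  seed; BN γ = 1, β = 0.
* CLAHE: per-tile histograms are clipped at
  `max(1, clip_limit · tile_pixels / 256)` with the excess redistributed
  uniformly; LUTs are kept in floating point and pixels are mapped by
  bilinear interpolation between the four nearest tile LUTs, rounding
  half-up once at the end. A constant image therefore stays constant.
* Median filter and CLAHE padding use symmetric (edge-including)
  reflection.
* ROI rescaling is bilinear with align-corners index mapping, so a
  same-size input round-trips unchanged and constants are preserved.
* Metrics: precision of a never-predicted class is defined as 0 (not NaN),
  F1 as 0 when precision + recall = 0; table comparisons round half away
  from zero to 4 decimals, matching how published tables are printed.
* ROC/PR: threshold sweep over the unique scores, trapezoidal areas.
* Degenerate inputs fail loudly: all-dark ROI windows raise a
  degenerate-ROI error (callers skip and log), an empty breast mask and
  single-class ROC truth are errors, and a non-finite training loss names
  the epoch.

## The synthetic phantom: what it emulates, and what a green test proves

`generate_image()` produces a MIAS-format world: a breast-shaped bright
half-ellipse attached to the left edge of a dark background, smoothed
Gaussian tissue texture (scale 16 px, sd 8 intensity units, clipped at
3 sd), optional lesions as radially tapered bright blobs (flat core to
60% of the radius, cosine taper to the rim, peak +60 over the base
intensity, radius 8–40 px), salt-and-pepper impulse noise (rate 0.01) for
the median filter to remove, and annotations in bottom-left-origin
coordinates. Two generator properties are contracts, and tested: lesions
are brighter than a surrounding same-area ring by at least half the
contrast, and lesion circles lie inside the default breast mask.

Two generator parameters deserve an explanation. The texture amplitude is
kept well below the lesion contrast because CLAHE amplifies whatever local
contrast exists: with texture at sd 12 and scale 8 px, enhanced texture
blobs became metrically similar to small lesions and the generator
violated its own separability contract (tumor ROI statistics must
stochastically dominate normal ones *and* support the end-to-end accuracy
property). And lesion centers keep at least 60 px (one ROI half side) from
every image edge: at the desk-scale image side of 256 the breast ellipse
touches the left border, so unconstrained centers produced *clamped* ROI
windows whose lesions sat far off-center — half the patches of such an ROI
contain no lesion at all, poisoning the patch labels. Real 1024-pixel
films place lesions well inside the image, so the constraint restores,
rather than bends, realism. Both choices are `phantom_config()` fields
(`texture_sd`, `center_margin`).

What the phantom does *not* emulate: X-ray physics, pectoral muscle,
calcification clusters, spiculated margins, vessel and fiber clutter, or
benign/malignant texture differences. A green end-to-end test therefore
establishes that the pipeline's plumbing, training dynamics, voting and
evaluation work and that the method separates separable classes — it says
nothing about clinical performance on real mammograms, which requires the
real archive and a pretrained backbone.

## Known limitations

* No pretrained VGG weights offline: `pretrained = TRUE` raises a
  dependency error; random frozen backbones stand in. Reproducing the
  published MIAS accuracy tables is out of scope by design.
* The `tiny_test` backbone's random features bound achievable patch
  accuracy; the phantom experiment compensates with clearly separable
  classes.
* Patch sampling is with replacement on a 49² offset lattice; at 2000
  patches per abnormal ROI some duplicates are expected (and harmless).
* Splits stratify by ROI label only — with one ROI per phantom image this
  equals a per-image split, but on a real archive with several
  abnormalities per film, film-level leakage across splits is possible.
* `evaluate_rois()` reuses one patch sample per ROI for both the vote and
  the ROC score; `classify_roi()`/`roi_tumor_score()` draw independently
  when called directly.
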