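---
title: "Automated pituitary-adenoma volumetry: models and methods"
author: "AdenoVol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pituitary-adenoma volumetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pituitary adenomas are treated by transsphenoidal resection, and the
clinically relevant quantity after surgery is the extent of resection
(EOR): the percentage of the preoperative tumor volume that was removed,

$$\mathrm{EOR} = 100\cdot\frac{V_{\mathrm{pre}} - V_{\mathrm{post}}}{V_{\mathrm{pre}}},$$

with gross total resection (GTR) defined strictly as EOR = 100%, i.e.
zero residual volume. Manual slice-by-slice segmentation of T1-weighted
contrast-enhanced MRI is slow and, particularly for small postoperative
residuals, poorly reproducible between raters. AdenoVol implements an
automated pipeline: conform each volume to a canonical grid, segment the
tumor slice-wise with an ensemble of 2D U-Nets, clean postoperative masks
morphologically, and derive volumes, EOR, GTR classification and
segmentation-quality metrics.

Because no clinical images ship with the package, a seeded phantom
generator produces synthetic pre/postoperative study pairs with exact
ground truth; every stage of the pipeline is exercised end to end on those
phantoms.

## Grid conformation

All volumes pass through a deterministic chain before any learning:

1. **RAS reorientation.** Voxel axes are permuted/flipped so they increase
   towards Right, Anterior, Superior, with the affine updated so world
   coordinates are untouched. Only axis-dominant orientations are
   accepted; oblique acquisitions (off-dominant direction components above
   a relative tolerance, default `1e-4`) are rejected with a diagnostic
   rather than silently resampled.
2. **Isotropic resampling** to the target spacing (clinical default
   1.0 mm). Images are interpolated trilinearly; masks use
   nearest-neighbour interpolation so labels stay binary. The field of
   view is preserved to within one voxel per axis.
3. **Shape conformation** to the canonical lattice (clinical default
   256^3) by centre crop and/or symmetric pad — images pad with their
   minimum intensity, masks with 0, and an odd leftover voxel goes to the
   high-index side.
4. **Per-study intensity normalization.** The normalization is a
   whole-volume z-score: it is the standard choice for CNN inputs, has no
   tunable parameters, and is invariant to positive affine intensity
   rescaling, which is what "normalized for each study individually"
   needs to achieve across scanners. Constant volumes map to zero.

Two orderings of reshaping and spacing normalization are conceivable; the
package fixes reorient → resample → conform because conforming first and
resampling later would change the physical field of view that the fixed
shape is meant to standardize.

"Coronal" slicing is defined on the RAS frame: one slice per position
along the anterior–posterior (second) axis, ascending, each slice a
right–left × superior–inferior matrix. `stackCoronal()` inverts the
operation voxel-exactly.

The canonical grid is a `GridSpec` value rather than a constant, so the
test suite and the examples below run the identical code paths at 64^3 or
16^3.

## The segmentation model

Segmentation is slice-wise 2D: each coronal plane is an independent
sample. The network is a compact U-Net — an encoder of repeated
(3×3 convolution + ReLU) pairs with 2×2 max-pooling between resolution
levels, a decoder with nearest-neighbour upsampling and skip
concatenations, and a final 1×1 convolution producing one logit per
pixel. The loss is binary cross-entropy (applied through a sigmoid), the
optimizer Adam, matching the standard recipe for this architecture. The
layers (im2col convolution with its backward pass, pooling, upsampling)
are implemented in the package's own compiled code, which keeps training
bit-reproducible from a single seed; a numerical-differentiation test
pins the convolution gradients.

Architecture size and schedule are configurable (`TrainConfig`), with
clinically-plausible defaults (depth 4, 16 base filters, learning rate
1e-3, batch 8) and deliberately small settings in the tests. Slices whose
masks are empty are *kept* in training: the postoperative task is
dominated by tumor-free slices and the model must learn to output empty
maps.

Training is patient-level five-fold cross-validation: `makeFolds()`
shuffles patient ids under a seed and deals them round-robin, so fold
sizes differ by at most one and both scans of a patient share a fold. One
master seed fans out to the fold split, weight initialization, shuffling
and augmentation; identical configurations reproduce loss histories and
weights exactly.

**Transfer learning.** Postoperative models can be initialized with the
parameters of fully trained preoperative fold models. The contract is
exact: before its first training step the recipient's predictions are
bit-identical to the donor's, and later recipient training never mutates
the donor.

**Augmentation.** An optional transform applies one random rotation in
[0, 90] degrees and one zoom-in of 0–30% to a sampled fraction of
training slices — image bilinear, mask nearest-neighbour, same transform
for both. The sampling ratio defaults to 1/255, read as the fraction of
slices augmented per epoch; it is a plain configuration value, so other
readings cost one argument.

## Ensemble inference and thresholds

At inference every fold model predicts every coronal slice; the restacked
probability grids are averaged voxel-wise with equal weights, and the
mean is binarized at a phase-specific cutoff: **0.6 preoperative, 0.44
postoperative**. Ties at the threshold count as foreground (a fixed,
documented convention; thresholding is monotone, so raising the cutoff
never adds voxels). Since thresholding is voxel-wise it commutes with
restacking; the package restacks first, then thresholds.

## Postoperative postprocessing

Postoperative predictions — many small, noisy residual candidates — pass
through three steps in this order:

1. **Small-component removal**: 26-connected components with fewer than
   50 voxels are deleted (50 mm^3 at canonical spacing). A component of
   exactly 50 voxels survives. The floor is counted in the 3D conformed
   grid, not per 2D slice, because the downstream quantity is 3D
   volumetry.
2. **Hole filling**: background regions with no 6-connected path to the
   lattice boundary become foreground.
3. **Dilation** by a 3×3×3 cube, one pass, smoothing corners towards more
   natural tumor shapes.

Connectivity choices (26 for components, 6 for holes) and the structuring
element are configurable; the defaults are the common morphological
conventions. After dilation components can merge or re-grow, so the size
floor is only guaranteed before the final step. Preoperative masks are
not postprocessed.

## Evaluation metrics

For masks $A$ and $B$: Dice $= 2|A\cap B|/(|A|+|B|)$, Jaccard
$= |A\cap B|/|A\cup B|$ (so $J = D/(2-D)$ pointwise), and HD95 — the
maximum of the two directed 95th-percentile surface distances in mm.
Surfaces are foreground voxels with at least one background 6-neighbour,
with the lattice border counting as background; distances are Euclidean
in world units and the percentile is the linear-interpolation quantile.

Empty masks need conventions, and aggregate tables change meaning with
them, so they are explicit and configurable:

* both masks empty → Dice = Jaccard = 1 and HD95 = 0 by default (the
  prediction is exactly right); `bothEmpty = 0` scores such pairs 0
  instead, for comparability with schemes that treat empty predictions as
  failures — with many true-GTR cases either reading materially changes a
  cohort mean;
* exactly one mask empty → Dice = Jaccard = 0 and HD95 = NaN (the
  distance to an empty surface is undefined).

`summarizeMetrics()` therefore exposes both a NaN-propagating and a
NaN-excluding mode.

Volumetry is voxel counting: volume = foreground count × voxel volume.
EOR uses the formula above and is *not* clamped — a predicted
postoperative volume exceeding the preoperative one yields a negative
EOR, preserving outliers in summaries. GTR is strictly
`postopVolume == 0`; near-zero residuals are not rounded up to GTR.
Confusion statistics take GTR-present as the positive class (sensitivity
is the GTR detection rate); rates with zero denominators are NaN rather
than an arbitrary 0 or 100. Correlations are Pearson product-moment via
`stats::cor`.

## The phantom generator

`makePhantom()` builds, deterministically from `(seed, patientId)`:

* a tumor mask: the union of 1–3 overlapping ellipsoids with jittered
  centres — one lobe gives an exact analytic volume $\frac43\pi abc$ for
  cross-checks, several give non-trivial connected shapes (their
  reference volume is computed on a 2× supersampled lattice);
* a preoperative image: smooth low-frequency background + Gaussian noise
  (SD 1) + a constant contrast offset (default 3) on the tumor,
  emulating an enhancing adenoma;
* a postoperative pair via `simulateResection()`: the residual is a
  6-connected region of exactly `round(f * preopCount)` voxels grown by
  breadth-first search from a surface voxel extremal along a random
  direction — a residual rim at one side of the resection cavity; the
  image regenerates with contrast only on the residual.

Cohort defaults are chosen once to resemble the reported clinical cohort
at desk scale: a 64^3 mm grid; semi-axes 6–14 mm (single-lobe volumes
roughly 1–11 ml, matching reported preoperative volumes of a few ml);
residual fractions of 2–15% for non-GTR cases, with a configurable
fraction (default one half, to exercise both sides of the GTR confusion
matrix) of exact GTR cases whose postoperative masks are empty — most
clinical postoperative volumes in this setting are zero or a small
fraction of the preoperative volume.

What the phantoms deliberately do **not** model: MRI physics (bias
fields, Rician noise), sellar anatomy, cavernous-sinus invasion geometry,
inter-scanner variation, or ambiguous residual enhancement. Passing
end-to-end tests on phantoms therefore demonstrates that the machinery —
conformation, training, ensembling, thresholding, postprocessing,
volumetry — is correct and reproducible, not that the bundled small
U-Net would reach clinical accuracy; on real scans the published
experience is that preoperative segmentation works well while small
postoperative residuals remain hard.

## Numerical choices and degenerate inputs

* Reorientation rejects non-invertible or oblique affines; resampling
  rejects axes shorter than two voxels; EOR and GTR reject zero
  preoperative volumes.
* Resampling clamps sample coordinates at the lattice border
  (edge-extend).
* The z-score guard maps volumes with SD < 1e-12 to all zeros.
* Thresholding uses `>=`; quantiles are type-7; the carve in
  `simulateResection` hits its voxel-count target exactly (0 gives an
  exactly empty mask).
* Training aborts with a diagnostic on non-finite loss rather than
  continuing from a poisoned state.

## Problem sizes used by the tests and acceptance script

The test suite trains on 16^3 phantoms (seconds) for unit-level training
properties, and one scaled-down study: 40 phantoms at 64^3, five-fold
preoperative training with a small network (depth 2, 4 base filters, 3
epochs, learning rate 3e-3, seed fixed), ensemble prediction of the 8
held-out phantoms at threshold 0.6. On this easy synthetic task the
sanity floors are median Dice at least 0.7 and automated-vs-true
preoperative volume correlation at least 0.8. The acceptance script runs
the same study with both phases (2 epochs) and additionally reproduces
the GTR confusion worked example: among all 2×2 matrices with n = 20,
exactly one — (TP, FN, FP, TN) = (6, 3, 7, 4) — has sensitivity rounding
to 66.67% and specificity to 36.36%, and its derived rates (accuracy
50.00%, PPV 46.15%, NPV 57.14%) follow from the counts.

## Known limitations

* The hand-rolled U-Net is CPU-bound and meant for moderate grids and
  desk-scale experiments, not for 256^3 clinical training runs.
* Slice-wise 2D modelling ignores through-plane context; 3D
  architectures are out of scope.
* No bias-field correction, skull stripping, or pre/post registration:
  inputs are assumed to be reasonably clean T1 contrast-enhanced volumes.
* The phantom generator's realism limits are listed above; clinical
  validation requires clinical data.
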