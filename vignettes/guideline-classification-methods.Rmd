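---
title: "Methods: guideline-aware classification and evaluation of radiotherapy structure sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guideline-aware classification and evaluation of radiotherapy structure sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Deep-learning segmentation models for radiotherapy organs at risk (OARs)
need training delineations drawn under one coherent guideline. In
practice an archive mixes guidelines — clinical contours next to
AI-generated ones, older protocols next to newer — and the structure
*name* carries no reliable information about which guideline produced
the contour. `oarclass` implements an image-based answer: classify each
structure from the CT and its binary mask, at the granularity of
*organ × guideline*, with a catch-all `"Other"` class, and demonstrate
on controlled synthetic data why the distinction matters — a
segmentation learner trained on a 50/50 guideline mixture is measurably
worse than one trained coherently.

## The preprocessing model

Each structure becomes a two-channel fixed-size 3D sample:

1. **Z-score normalization.** Mean and standard deviation are computed
   over voxels with HU strictly above the air threshold (−1000 HU) and
   applied to all voxels. The *population* standard deviation is used:
   at CT voxel counts the sample/population distinction is below 1e−5
   relative and population is the common imaging convention. The
   statistics are computed *before* resampling, fixing the published
   order of operations.
2. **Resampling.** Intensities are resampled with separable quadratic
   (order-2) B-spline interpolation — a recursive single-pole prefilter
   (pole √8 − 3, mirror boundaries) followed by the 3-tap B-spline
   kernel, which is exact at source grid points; masks use nearest
   neighbor and stay binary. "Bi-quadratic" in-plane behaviour is
   interpreted as order-2 splines applied per axis in 3D. The output
   grid is `n_out = round(n_in · sp_in / sp_out)` per axis with the
   origin preserved, so physical extent is kept to within one voxel.
3. **Body masking and cropping.** Everything outside the body contour
   (couch, immobilization) is set to 0 — the fill value 0 is chosen to
   coincide with the AddMap background and the zero padding — and the
   grids are cropped to the body's bounding box.
4. **AddMap.** The joint encoding `(body + structure) / 2`: 1 where
   body and structure overlap, 0.5 in the body only, 0 in the
   background. Its codomain {0, 0.5, 1} is asserted on every sample.
5. **Slice window.** A structure spanning more than `slice_cap` nonzero
   slices is ignored (96 slices × 3 mm = 288 mm inferior–superior
   support on the clinical profiles; the bound is strict, so exactly 96
   slices is still eligible). Otherwise a window of exactly `slice_cap`
   slices is centered at the midpoint between the first and last
   nonzero slice, rounded up at half-slices — rounding up (not down)
   is what keeps every nonzero slice inside the window when the
   structure's extent equals the cap exactly. At volume edges the window is zero-padded,
   not shifted, preserving the structure-centered property; the
   rounding conventions (midpoint up, odd padding remainder to the
   high-index side) are documented choices where the source protocol
   is silent.
6. **Pad / downscale.** Smaller dimensions are symmetrically
   zero-filled to the profile grid (184 × 280 × 96 bowel profile,
   200 × 328 × 96 pelvis profile). An in-plane overflow is a fatal
   error during training; at inference the in-plane axes are downscaled
   by nearest neighbor, preserving the AddMap codomain.

## Training protocol

The loss is weighted categorical cross entropy with "balanced"
inverse-frequency weights `w_c = N/(K·n_c)`. Model selection and early
stopping use the **custom precision** `CP = Σ_{i≠j} P_i` — the sum of
per-class precisions excluding the `"Other"` class (index j); a class
with no predicted instances contributes 0, a conservative choice for a
stopping criterion. Adam starts at 1e−4 (clinical profiles); the
learning rate is halved when the validation loss shows no improvement
for 15 epochs; training stops when validation CP has not improved for
60 epochs (bowel profile) or 20 (pelvis), and the weights of the
best-CP epoch are kept. Augmentation is 2D in-plane — left-right flip
(bowel profile only; the pelvis vocabulary contains lateralized
classes), rotation within ±5°, translation within ±10 px — each
applied independently with probability 0.5 (bowel) or 0.4 (pelvis),
composed into one nearest-neighbor affine map applied identically to
both channels, so the AddMap codomain survives augmentation.
Cross-validation is 5-fold with an 80%/20% split **at patient level**
(the published protocol does not state the split unit; patient-level
prevents sibling structures from straddling the split).

## The backbone contract and the desk-scale reference

The classifier backbone is a contract: any object that builds a model
mapping a two-channel grid to a probability vector can be dropped in;
the published full-scale network (a 154-layer squeeze-and-excite
ResNeXt) is intentionally out of scope. The shipped desk-scale
reference is a compact 3D CNN built from first principles (no
deep-learning framework exists in the supported R stack): block
average-pooling of the input, two same-padded 3×3×3 convolutions
(ReLU, the second with stride 2), and a softmax head over the
*flattened* coarse feature map. Flattening rather than global average
pooling is a deliberate deviation from the obvious sketch: global
pooling destroys spatial position, and left vs right femoral head is a
position-only distinction. Convolutions are precomputed sparse im2col
gather matrices (Matrix package) so that training is dense BLAS work;
gradients were verified against numerical differentiation at 1e−7
relative error.

## Desk profile

Grading runs on one CPU in minutes, so the package adds a `"desk"`
profile next to the clinical `"bowel"`/`"pelvis"` profiles: 6 mm
isotropic spacing, 24-slice cap, 40 × 44 × 24 grid, Adam at 3e−3,
CP patience 6, 30-epoch cap, batch 8, translation ±4 px, no flip.
These values were fixed once for the compute budget and are not tuned
to any acceptance threshold; the clinical profiles keep the published
values.

## The phantom world

The synthetic cohort emulates the *geometry* of the problem, not
anatomy. A phantom is an elliptical soft-tissue body (40 HU) with a
thin fat shell (−100 HU), air background at exactly −1000 HU, a couch
slab outside the body (200 HU), bone-density femoral spheres with
shafts (700 HU), and organs with mild intrinsic contrast (bladder 10,
rectum −30, bowel 25 HU). Gaussian noise (σ = 10 HU) applies to voxels
above the air floor only — scanner-calibrated air sits at the −1000 HU
floor, which is exactly the property the z-score air threshold relies
on. Guideline variant A is the base shape; variant B applies an
in-plane dilation of 6 mm plus 4-slice superior and inferior
extensions — except the bladder, where B is a 6 mm in-plane *erosion*
(emulating bladder-wall exclusion, so B ⊂ A for that organ). At 6 mm
voxels, 6 mm is the smallest non-degenerate dilation radius. Each
patient carries both variants of every organ (as when a commercial
model adds contours next to clinical ones), plus nuisance structures
with clinical-style names containing exclusion keywords ("PTV_68",
"Ring_PTV", "Opt_ring", …) and one cleanly named distractor, all
labelled `"Other"`; the body itself is the masking reference and is
not a classification sample. Per-patient jitter moves organ centers
and scales axes; a fixed seed reproduces a phantom bit-identically.

What a green phantom test does **not** establish: clinical effect
sizes. Phantom class separation is parametric and generous; real
guideline differences interact with anatomy, scanners and observers.
The phantoms establish that the *pipeline* — preprocessing, loss,
CP-driven selection, voting, exclusion — recovers planted structure.

## Inference

Every eligible structure is classified by each of the five fold
models; majority voting picks the label, ties broken by the highest
summed probability across folds and then by vocabulary order (the
published method does not state tie handling for five voters over
more than two classes). Optional **structure-name exclusion** then
forces `"Other"` whenever the lowercased stored name contains any
profile keyword as a plain substring — no regular expressions. Because
exclusion only ever maps labels *toward* `"Other"`, the precision of
every non-Other class is non-decreasing under it; this directional
property is asserted on phantom cohorts. Files are copied into
per-class folders by the final (post-exclusion) label.

## The mixed-guideline demonstration

Three segmentation learners are trained on demo-scale phantoms
(32 × 32 × 24 at 9 mm; dilation 9 mm and ±3-slice extensions so the
guideline offset is at least one voxel in every direction): coherent-A,
coherent-B, and a 50/50 patient-level mixture. Each is a 5-fold
ensemble, reduced by the voxel-wise mean of fold probability maps
thresholded at 0.5 (the published work names an "average model
ensemble" without stating the reduction). Evaluation on held-out
phantoms applies the pipeline's own conventions — prediction restricted
to the body, largest 6-connected component, superior truncation at the
ground truth's top slice — before DSC, HD95 and MSD, and compares
coherent vs mixed per guideline with the exact two-sided Wilcoxon
signed-rank test.

The learner itself is a deliberate desk-scale substitution for the
prior-work pelvic U-Net (explicitly out of scope): a fixed two-level
mean-pooling pyramid (2× and 4× blocks, nearest-neighbor upsampled)
plus vertically shifted copies of the 2× level — the inferior/superior
axis is where guideline B extends — fused by a learnable pointwise
(1×1×1) network with a sigmoid head, trained with foreground-weighted
(w = 4) binary cross entropy on body voxels only, Adam 1e−2, early
stopping on validation loss. A strided encoder–decoder CNN was tried
first and either collapsed to background or oversegmented within the
CPU budget; the pyramid design keeps the ~3-voxel context the
parametric offsets require while training a fold in seconds. The
demonstration's claim is directional only (mixed worse than coherent
on DSC, HD95 and MSD); the clinical magnitudes depend on the clinical
cohort and are out of scope.

## Geometric metrics and statistics

Surfaces are boundary voxels under 6-connectivity (a mask voxel with a
face neighbor outside the mask or the volume); distances are between
voxel centers in physical mm. HD95 is the 95th percentile — linear
interpolation, R's default quantile type 7 — of the *pooled* symmetric
distance distribution; MSD is the mean of the two directed mean
distances. Both conventions are decisions where the source protocol is
silent, and both are verified against an independent all-pairs
brute-force oracle to 1e−9 on small masks. Dice of two empty masks is
defined as 1 with a flag; HD95/MSD on an empty mask are errors. The
Wilcoxon signed-rank test drops zero differences, enumerates all 2^n
sign assignments exactly for n ≤ 12 (average ranks on ties), and uses
the tie-corrected normal approximation with continuity correction
beyond; it is cross-checked against `stats::wilcox.test`.

## Numerical and degenerate-input choices

- Z-score on a volume with fewer than 2 voxels above the air
  threshold, or zero spread, is a fatal error.
- An empty body mask is fatal; empty structures are dropped at load
  time with a warning (they carry no geometry to classify).
- Zero probability at the true class is clamped at 1e−12 with a
  message.
- Duplicate body candidates ("BODY" and "External" both present):
  first in file order wins, with a warning — a decision, not recovered
  intent.
- Body-name matching is case-insensitive exact match on
  {"BODY", "External"}.
- An empty demo prediction is recorded as DSC 0 with missing HD95/MSD
  and a warning, and excluded from means.

## Known limitations

The DICOM codec is deliberately minimal (explicit VR little endian,
single-frame CT, CLOSED_PLANAR RT-STRUCT contours) — enough for the
phantom exporter round trip that the cross-format equivalence test
requires, not a general DICOM implementation. The NIfTI codec ignores
orientation codes beyond a diagonal sform. No intensity harmonization,
metal-artifact handling, MRI support, or anonymization. The desk-scale
backbone is not expected to match full-scale published accuracies —
only the pipeline properties around it.
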