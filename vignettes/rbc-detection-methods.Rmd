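---
title: "Detecting red blood cells in smear images: models, parameters and design choices"
author: "rbcdetect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting red blood cells in smear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcdetect)
```

# The problem

Stained blood smears show red blood cells (RBCs) as roughly circular,
often touching or overlapping discs, darker than the illuminated
background. Counting and localizing them underpins complete-blood-count
style analyses, and manual counting is slow and error-prone. `rbcdetect`
implements a full detection pipeline for this setting — denoising,
classical threshold/morphology segmentation, a small trainable
region-proposal detector, post-detection plausibility scoring, and
IoU-based evaluation — together with a synthetic smear generator that
provides exact ground truth, so every stage is testable end to end without
any external dataset.

# Bilateral filtering and the radial gradient index

Smear images carry sensor noise that plain smoothing would pay for with
blurred cell borders. The bilateral filter weights each neighbor $(p,q)$
of pixel $(i,j)$ by the product of a spatial Gaussian and an intensity
("range") Gaussian,

$$w(i,j,p,q) \;=\;
\exp\!\Big(-\tfrac{(i-p)^2+(j-q)^2}{2\sigma_d^2}\Big)\,
\exp\!\Big(-\tfrac{(I(i,j)-I(p,q))^2}{2\sigma_r^2}\Big),$$

and replaces $I(i,j)$ by the $w$-weighted average of its neighborhood,
normalized by the weight sum $W(i,j)$. Pixels across an edge differ in
intensity, receive negligible range weight, and therefore do not bleed
into each other: noise is averaged away within regions while borders
survive.

Parameters, with defaults chosen for unit-scaled images and cell-scale
structure: `sigma_d` (pixels, default 1.5) sets the spatial reach;
`sigma_r` (intensity units, default 0.1) sets how large an intensity jump
counts as an edge — roughly a fifth of the cell/background contrast of a
typical stained smear; the window is truncated at
`ceiling(3 * sigma_d)` pixels where the spatial weight has decayed to
under 1% (the summation over the full image that the defining formula
writes is numerically indistinguishable from this truncated sum, and the
naive-evaluation oracle in the test suite uses the same window so the
equivalence check is exact); borders use neighborhood clipping, with $W$
adjusting, rather than invented padding. `iterateFilter()` applies the
filter repeatedly (default cap 10 passes) and stops when the mean absolute
change per pixel drops below `convergence_tol` (default $10^{-4}$, i.e.
well under one gray level of an 8-bit image).

The *radial gradient index* (RGI) scores how blob-like the neighborhood of
a point is: over a disc, it averages the cosine of the angle between the
local intensity gradient and the outward radial direction. A radially
symmetric dark-center cell gives $+1$ (all gradients point outward toward
the brighter surround), a bright-center blob $-1$, and structureless or
one-sided context about $0$ by cancellation. We deliberately average
*directions only* rather than magnitude-weighting: magnitude weighting
makes the score strongly negative for a disc placed merely *near* a dark
blob (the near-side gradients dominate and point anti-radially), which
would defeat its use as an "is this centered on a blob?" test. With the
direction-only mean, off-center placements score near zero, which is the
behavior the detection filter relies on. Pixels with exactly zero gradient
contribute zero, and a fully flat disc scores 0 by convention.

# Threshold and morphology segmentation

Segmentation follows the classical chain on a grayscale image $I$ with
threshold $T$ (Otsu's between-class-variance criterion over a 256-bin
histogram by default, or a fixed value):

* background $B(i,j) = 1$ iff $I(i,j) > T$; foreground $F(i,j) = 1$ iff
  $I(i,j) \le T$ — the boundary value is foreground, so *dark* cells are
  foreground; a `polarity` switch inverts the image first for bright-cell
  imagery;
* erosion of $B$ and dilation of $F$ over a structuring element $S$
  (default $3\times3$ square), with out-of-bounds neighbors treated as 0
  in both operations — a symmetric convention under which the
  erosion/dilation duality holds exactly on interior pixels;
* combination $R = 1$ where the dilated foreground is set and the eroded
  background is not;
* 8-connectivity component labeling of $R$, discarding components smaller
  than `min_area` (default 30 px, about a quarter of the smallest
  plausible cell at these scales), with per-region tight boxes, areas and
  centroids.

Two properties of this exact chain are worth knowing. First, in the image
interior the combination step reduces algebraically to the dilated
foreground, so the chain *expands* every object by one structuring-element
radius; two objects separated by two pixels or less merge by construction,
not by error. The synthetic generator therefore defines "non-overlapping"
placement as a clearance of at least 3 px between cell supports — with a
tighter definition, exact count recovery would be impossible for any
implementation of this chain. Second, the conventional alternative
(morphological opening of the foreground) is available via
`segmentCells(mode = "opening")` for users who prefer a non-expanding
refinement.

# The region-proposal detector

Touching and overlapping cells defeat pure thresholding, which is why the
package also provides a learned, region-based detector in the two-stage
style: a convolutional backbone shared by (i) a region proposal head that
scores a grid of anchor boxes and regresses corrections, and (ii) an RoI
head that classifies pooled proposal features and refines the boxes.

All geometric stages are exported and tested individually:

* `generateAnchors()` tiles one anchor per lattice cell, scale and aspect
  ratio; defaults are stride 8 with square anchors of side 12, 20 and
  32 px, bracketing the cell diameters the generator produces (10–18 px).
* `decodeBoxes()`/`encodeBoxes()` use the standard center/log-size
  parameterization, so zero coefficients are exactly the identity.
* `filterProposals()` clips coordinates to the image, removes boxes below
  `min_size` (default 8 px), and keeps the `pre_nms_topN` (default 6000)
  highest-scoring proposals, stable on ties.
* `nmsBoxes()` is greedy non-maximum suppression (proposal IoU threshold
  0.7; final per-class suppression at 0.3), keeping `post_nms_topN`
  (default 300).
* `roiPool()` max-pools each proposal into a fixed bin grid with outward
  quantization; empty bins of degenerate RoIs yield 0.
* `multitaskLoss()` is the mean softmax cross-entropy plus
  $\lambda_{loc}$ (default 1) times the per-positive mean of coordinate-
  summed smooth-L1 ($\beta = 1$) box errors; with no positive samples the
  localization term is 0.

The backbone is deliberately small — three 3×3 convolution + 2×2 max-pool
stages (8, 16, 32 channels) plus one extra 3×3 convolution at stride 4 —
so that training 200 small scenes takes minutes on one CPU core with no
GPU and no pretrained weights. Anchor training targets follow the usual
IoU rule (positive at ≥ 0.7 or as a truth box's best anchor provided the
overlap reaches 0.1, negative at ≤ 0.3, the rest ignored), with a balanced
sample of 64 anchors per image, optimized with Adam (lr $10^{-3}$,
decayed ×0.3 for the final 30% of epochs; default 12 epochs).

Two design choices came out of the open design space and are worth
recording:

* **RoI features come from the stride-4 map with a 4×4 bin grid.** At
  stride 8 a 12-px cell spans barely two feature cells; pooled 2×2
  features cannot express whether a box is centered on a cell or offset by
  a third of its width, and box refinement stalls around IoU 0.5. The
  stride-4 map resolves this while the stride-8 map still drives the
  proposal head.
* **The RoI head trains on a deliberately mixed RoI diet**: the truth
  boxes, jittered copies (so refinement sees the errors it must undo),
  *hard negatives* offset by 30–60% of the box size (the regime where
  confident duplicate detections would otherwise live), the current RPN's
  own top proposals (so the head scores the distribution it will face at
  inference), and random background boxes. Labels come from each
  candidate's actual IoU with truth: foreground at ≥ 0.55, background
  below 0.45, the narrow band between discarded. The head is trained on
  pooled features without backpropagating through the pooling into the
  backbone; the proposal pathway trains the backbone end to end.

At inference the head refines boxes twice, re-pooling after each pass, so
near-duplicate proposals converge onto the same box and are removed by the
final NMS, and the reported score belongs to the reported box. Detections
below `score_threshold` (default 0.5) are dropped, and by default the
post-network RGI filter (below) is applied; both are switchable.

`labelCells()` implements the final labeling step: detections surviving a
filtering model — score threshold, center-disc RGI at least 0, and area
within 0.25–4× the median detected area — are rasterized as the set union
of their boxes into a binary mask.

# Post-network operations

Raw detections pass through optional scoring and filtering stages, in the
order score → RGI filter → ranking:

* `rgiRegionFilter()` keeps detections whose center disc (radius half the
  box's smaller side) has RGI at least a threshold (default 0) — a cheap
  "is there actually a blob here" test.
* `fractalDimension()` estimates the box-counting (Minkowski–Bouligand)
  dimension of a region's binarized patch by regressing log box count on
  log inverse box size over dyadic sizes. Solid cell-like regions score
  near 2, thin artifacts near 1, isolated specks 0; it is used purely as a
  plausibility feature.
* `scoreRegions()` min–max normalizes the detector score, RGI and fractal
  dimension across the detection set (a constant component maps to 0.5)
  and ranks by the weighted sum, default weights 0.6/0.3/0.1 — the
  detector score carries most of the evidence, RGI is an independent shape
  check, and the fractal term is a weak tie-breaker.

# Augmentation

`augmentConfig()` holds the standard affine augmentation parameters
(rotation range in degrees, width/height shifts as fractions, shear in
radians, zoom as $1 \pm$ range, horizontal flip, fill mode; defaults 0.2°,
0.2/0.1, 0.1, 0.5, on, nearest). `sampleTransform()` composes one random
draw into a single affine map about the image center; `applyTransform()`
warps the image by inverse-mapped bilinear resampling and maps each
ground-truth box by transforming its corners and taking the axis-aligned
hull, clipped, dropping boxes that collapse to zero area. The intensity
`rescale` factor defaults to 1 because in-memory images are already unit
scaled; `1/255` is the appropriate setting when feeding raw 8-bit arrays.
Augmentation is intended for training data only.

# The synthetic generator, and what it does not show

`generateScene()` renders elliptical cells (semi-axes 8–14 px by default,
eccentricity up to 0.4) with a raised-cosine edge profile onto a
background with a mild linear illumination ramp, then applies
multiplicative speckle and additive Gaussian noise, clipped to $[0,1]$.
Cells are darker (0.35) than the background (0.85), matching the
foreground convention above. A target fraction of cells is placed in
touching pairs (attached at center distance 0.55–0.9 of the summed radii);
the rest are placed by rejection sampling with ≥ 3 px clearance and a
bounded retry count, failing loudly on infeasible packings. Instance
labels partition the union of supports by nearest normalized elliptic
radius, and boxes are recomputed from the final mask, so each box is
exactly tight.

The generator emulates the features that matter for testing this
pipeline — cell-like blobs, clusters, intensity inhomogeneity, two noise
types, exact truth — and nothing more. It does not model staining
variability, defocus, WBC/platelet morphology, debris, or the intensity
statistics of any real camera. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not clinical
performance on real smears.

Default problem sizes used by the test suite and the reproduction script:
segmentation recovery uses 200×200 scenes with 20 disks; detector training
uses 200 scenes of 64×64 px with 4 cells each (radius 5–9 px, 25%
clustered, noise σ 0.02, speckle 0.03) and evaluates on 50 held-out
scenes — sizes at which a full run of every stage completes in minutes on
a single core while still exercising clustering and noise.

# Evaluation protocol

`matchDetections()` performs greedy score-ordered matching (each
prediction to the highest-IoU unmatched truth at IoU ≥ 0.5 by default);
greedy matching is the standard convention in detection evaluation and
keeps counts interpretable: TP + FN always equals the number of truths,
TP + FP the number of predictions. `computeMetrics()` reports precision,
recall, F1 and a detection accuracy defined as TP/(TP+FP+FN); ratios with
zero denominators are reported as 0 and flagged. `makeSplits()` provides
both a 60/20/20 holdout (validation and test sizes round to nearest,
remainder to training) and k-fold cross-validation (fold sizes differing
by at most one, rotations disjoint and exhaustive), both deterministic
under a seed. Which protocol to use is left to the analyst; the package
asserts neither as canonical.

# Numerical conventions and degenerate inputs

* Boxes are 0-based half-open $(x_0, y_0, x_1, y_1)$ with $x$ along
  columns; a box's area is $(x_1-x_0)(y_1-y_0)$ and zero-area boxes have
  IoU 0 by definition. Pixel centers sit at half-integer coordinates.
* Bilinear resampling aligns pixel centers, so same-size resizing and
  identity warps are bit-exact and interpolation never overshoots the
  input range.
* Min–max normalization maps a constant image to all zeros rather than
  dividing by zero.
* Ties are broken by original index everywhere ordering matters (NMS,
  proposal ranking, region ranking), making every stage stable and
  reproducible.
* All stochastic stages (generator, augmentation, splits, training) take
  explicit seeds and restore the caller's RNG state; fixed seeds give
  bit-identical scenes, transforms, splits and training trajectories.

# Known limitations

* The segmentation chain cannot split touching cells (no watershed or
  distance-transform machinery); clusters are counted as one component by
  design, which is precisely the gap the trainable detector fills.
* The detector is desk-scale: a four-stage backbone trained from scratch
  on synthetic scenes. It demonstrates the architecture and training
  machinery faithfully but is not a clinical-grade model, and no
  pretrained weights ship with the package.
* RGI assumes dark-center cells; bright-field polarity must be handled by
  inverting the image first.
* The fractal dimension estimator assumes dyadic patch sizes (patches are
  zero-padded up to the next power of two) and is a coarse feature, not a
  rigorous dimension estimate.
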