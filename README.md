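# rbcdetect

Detection and counting of red blood cells (RBCs) in grayscale blood-smear
microscopy images, for researchers building or evaluating automated
blood-count pipelines. Stained smears show RBCs as roughly circular, often
touching discs, darker than the background; the hard parts are noise,
uneven illumination, and clusters of overlapping cells.

The package implements the full pipeline as tested, composable pieces:

* **Edge-preserving denoising** — a bilateral filter with weights
  `w = exp(-(Δi² + Δj²)/2σ_d²) · exp(-(ΔI)²/2σ_r²)`, applied iteratively,
  plus the **radial gradient index** (RGI), a blob score in [−1, 1] that
  averages the alignment between local gradients and the outward radial
  direction over a disc (+1 for a dark-center cell).
* **Threshold + morphology segmentation** — foreground `F = (I ≤ T)` and
  background `B = (I > T)` with Otsu's threshold, erosion/dilation over a
  structuring element `S`, combination
  `R = 1 ⇔ dilate(F) = 1 ∧ erode(B) = 0`, and 8-connectivity component
  counting with tight boxes.
* **A compact region-proposal detector** — anchors on a stride lattice,
  center/log-size box regression decoding, proposal clipping/size
  filtering/ranking (`pre_nms_topN = 6000`), greedy NMS
  (`post_nms_topN = 300`), RoI max pooling, and a multi-task loss
  (cross-entropy + smooth-L1), trained from scratch on CPU in minutes — no
  GPU, no pretrained weights.
* **Post-network operations** — region scoring and ranking by detector
  score, RGI and box-counting fractal dimension; RGI-based false-positive
  filtering; rasterization of surviving detections into a labeled mask.
* **Evaluation** — greedy IoU matching (`TP + FN = #truths`,
  `TP + FP = #predictions`), precision/recall/F1/accuracy, 60/20/20
  holdout and 10-fold cross-validation splits.
* **A synthetic smear generator** — elliptical soft-edged cells, touching
  clusters, illumination gradient, Gaussian + speckle noise, with exact
  instance masks and tight bounding boxes as ground truth.

## Worked example

```r
library(rbcdetect)

## a synthetic field with known truth: 20 non-overlapping cells
p  <- sceneParams(image_height = 200, image_width = 200, n_cells = 20,
                  radius_range = c(6, 10), overlap_fraction = 0,
                  noise_sigma = 0.05, speckle_strength = 0, seed = 7)
sc <- generateScene(p)

## classical segmentation with one bilateral pass
res <- segmentCells(sceneImage(sc),
                    filter_params = filterParams(n_iterations = 1))
res$count
#> [1] 20
head(res$regions, 3)
#>   label x0  y0 x1  y1 area       cx       cy
#> 1     1  4 181 18 195  163 10.97239 188.0337
#> 2     2 10 140 26 155  203 18.15517 147.5296
#> 3     3 43 137 63 158  345 53.10580 147.4826

## a trained detector handles touching clusters
pd     <- sceneParams(image_height = 64, image_width = 64, n_cells = 4,
                      radius_range = c(5, 9), overlap_fraction = 0.25,
                      noise_sigma = 0.02, speckle_strength = 0.03, seed = 1)
model  <- trainDetector(simulateScenes(200, pd, seed = 100), seed = 1)
held   <- simulateScenes(50, pd, seed = 5000)
ev     <- evaluateDetector(model, held, iou_threshold = 0.5)
round(unlist(ev$metrics[c("precision", "recall")]), 3)
#> precision    recall
#>     0.882     0.930
```

`res$count` is the number of connected cells recovered by the
threshold/morphology chain (here equal to the truth); `precision` and
`recall` are IoU-0.5 matched detection metrics of the learned detector on
held-out scenes with touching cells — the regime where pure thresholding
undercounts.

A command-line front end ships at `inst/cli/rbcdetect`
(`simulate`, `filter`, `segment`, `augment`, `train`, `detect`,
`evaluate`); run it with `Rscript` after installing the package.

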