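## Geometric primitives of the region-proposal detector: anchor generation,
## box-regression decoding/encoding, proposal clipping/size filtering/
## sorting, greedy non-maximum suppression, RoI max pooling, and the
## multi-task training loss. These are pure functions, independent of the
## learned network, and each is checked against a brute-force oracle in the
## test suite.

#' Proposal-stage configuration
#'
#' @param pre_nms_topN number of top-scoring proposals kept before NMS
#'   (default 6000).
#' @param post_nms_topN number of proposals kept after NMS (default 300);
#'   must not exceed `pre_nms_topN`.
#' @param min_size minimum proposal width/height in pixels after clipping.
#' @param nms_iou IoU threshold for proposal NMS, in (0, 1).
#' @return validated list of class `ProposalConfig`.
#' @export
proposalConfig <- function(pre_nms_topN = 6000, post_nms_topN = 300,
                           min_size = 8, nms_iou = 0.7) {
  if (post_nms_topN > pre_nms_topN)
    stop("post_nms_topN must be <= pre_nms_topN")
  if (nms_iou <= 0 || nms_iou >= 1) stop("nms_iou must be in (0, 1)")
  structure(list(pre_nms_topN = as.integer(pre_nms_topN),
                 post_nms_topN = as.integer(post_nms_topN),
                 min_size = min_size, nms_iou = nms_iou),
            class = "ProposalConfig")
}

#' Generate the anchor grid
#'
#' One anchor per (lattice cell, scale, ratio). Centers sit at the middle
#' of each stride-sized cell; for scale `s` and aspect ratio `r` the anchor
#' is `h = s * sqrt(r)`, `w = s / sqrt(r)` (area `s^2` for every ratio).
#' Anchors may extend beyond the image; they are clipped later by
#' [filterProposals()]. The anchor ordering matches the flattening of an
#' `(rows, cols, A)` score array: row index fastest, then column, then
#' anchor type.
#'
#' @param image_shape integer `(height, width)` in pixels.
#' @param stride lattice spacing in pixels.
#' @param scales vector of anchor side lengths in pixels.
#' @param ratios vector of aspect ratios (height/width).
#' @return matrix with columns `x0, y0, x1, y1`; attribute `grid` holds the
#'   lattice dimensions.
#' @export
#' @examples
#' nrow(generateAnchors(c(64, 64), 8, c(12, 20), 1))  # 128
generateAnchors <- function(image_shape, stride = 8, scales = c(12, 20, 32),
                            ratios = 1) {
  if (stride <= 0 || any(scales <= 0)) stop("stride and scales must be positive")
  if (length(scales) == 0L || length(ratios) == 0L)
    stop("scales and ratios must be non-empty")
  gh <- ceiling(image_shape[1] / stride)
  gw <- ceiling(image_shape[2] / stride)
  combos <- expand.grid(iy = seq_len(gh), ix = seq_len(gw),
                        a = seq_len(length(scales) * length(ratios)))
  sr <- expand.grid(scale = scales, ratio = ratios)
  s <- sr$scale[combos$a]; r <- sr$ratio[combos$a]
  cx <- (combos$ix - 0.5) * stride
  cy <- (combos$iy - 0.5) * stride
  h <- s * sqrt(r); w <- s / sqrt(r)
  out <- cbind(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2,
               y1 = cy + h / 2)
  attr(out, "grid") <- c(rows = gh, cols = gw,
                         A = length(scales) * length(ratios))
  out
}

#' Decode box-regression coefficients against anchors
#'
#' Standard center/log-size parameterization: for anchor center
#' `(xa, ya)` and size `(wa, ha)`, the decoded box has center
#' `xa + tx * wa`, `ya + ty * ha` and size `wa * exp(tw)`, `ha * exp(th)`.
#' All-zero coefficients return the anchors unchanged.
#'
#' @param anchors anchor box matrix.
#' @param regression matrix with columns `(tx, ty, tw, th)`, one row per
#'   anchor.
#' @return decoded box matrix.
#' @export
decodeBoxes <- function(anchors, regression) {
  anchors <- boxMatrix(anchors)
  regression <- matrix(regression, nrow(anchors), 4)
  if (any(!is.finite(regression))) stop("non-finite regression coefficients")
  wa <- anchors[, 3] - anchors[, 1]; ha <- anchors[, 4] - anchors[, 2]
  xa <- (anchors[, 1] + anchors[, 3]) / 2
  ya <- (anchors[, 2] + anchors[, 4]) / 2
  xc <- xa + regression[, 1] * wa
  yc <- ya + regression[, 2] * ha
  w <- wa * exp(regression[, 3]); h <- ha * exp(regression[, 4])
  cbind(x0 = xc - w / 2, y0 = yc - h / 2, x1 = xc + w / 2, y1 = yc + h / 2)
}

#' @describeIn decodeBoxes inverse operation: the coefficients that map
#'   each anchor onto the corresponding target box.
#' @param boxes target box matrix, one row per anchor.
#' @export
encodeBoxes <- function(anchors, boxes) {
  anchors <- boxMatrix(anchors); boxes <- boxMatrix(boxes)
  wa <- anchors[, 3] - anchors[, 1]; ha <- anchors[, 4] - anchors[, 2]
  xa <- (anchors[, 1] + anchors[, 3]) / 2
  ya <- (anchors[, 2] + anchors[, 4]) / 2
  w <- boxes[, 3] - boxes[, 1]; h <- boxes[, 4] - boxes[, 2]
  xc <- (boxes[, 1] + boxes[, 3]) / 2; yc <- (boxes[, 2] + boxes[, 4]) / 2
  cbind(tx = (xc - xa) / wa, ty = (yc - ya) / ha, tw = log(w / wa),
        th = log(h / ha))
}

#' Clip, size-filter and rank proposals
#'
#' Three steps, in order: (a) coordinates are clamped to
#' `[0, width] x [0, height]`; (b) boxes whose clipped width or height is
#' below `min_size` are removed; (c) the survivors are sorted by score,
#' descending, with ties broken by original index (stable), and the top
#' `pre_nms_topN` kept.
#'
#' @param boxes proposal box matrix.
#' @param scores numeric score vector, one per box.
#' @param image_shape integer `(height, width)`.
#' @param config a [proposalConfig()] list.
#' @return list with filtered `boxes`, `scores`, and the original `index`
#'   of each survivor.
#' @export
filterProposals <- function(boxes, scores, image_shape,
                            config = proposalConfig()) {
  boxes <- boxMatrix(boxes)
  if (nrow(boxes) != length(scores)) stop("boxes/scores length mismatch")
  if (nrow(boxes) == 0L)
    return(list(boxes = boxes, scores = scores, index = integer(0)))
  boxes <- clipBoxes(boxes, image_shape)
  keep <- (boxes[, 3] - boxes[, 1]) >= config$min_size &
          (boxes[, 4] - boxes[, 2]) >= config$min_size
  boxes <- boxes[keep, , drop = FALSE]
  scores <- scores[keep]
  idx <- which(keep)
  ord <- order(-scores)            # stable: ties keep original order
  ord <- ord[seq_len(min(length(ord), config$pre_nms_topN))]
  list(boxes = boxes[ord, , drop = FALSE], scores = scores[ord],
       index = idx[ord])
}

#' Greedy non-maximum suppression
#'
#' Boxes are taken in descending score order (stable on ties); each
#' accepted box suppresses all remaining boxes whose IoU with it exceeds
#' `iou_threshold`. At most `post_nms_topN` boxes are returned.
#'
#' @param boxes box matrix.
#' @param scores score vector.
#' @param iou_threshold suppression threshold in (0, 1).
#' @param post_nms_topN maximum number of boxes kept (`Inf` for all).
#' @return list with kept `boxes`, `scores` and original `index`.
#' @export
nmsBoxes <- function(boxes, scores, iou_threshold = 0.7,
                     post_nms_topN = Inf) {
  boxes <- boxMatrix(boxes)
  n <- nrow(boxes)
  if (n == 0L)
    return(list(boxes = boxes, scores = scores, index = integer(0)))
  ord <- order(-scores)
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (k in ord) {
    if (!alive[k]) next
    keep <- c(keep, k)
    if (length(keep) >= post_nms_topN) break
    iou <- boxIoU(boxes[k, , drop = FALSE], boxes[alive, , drop = FALSE])
    suppress <- which(alive)[iou[1, ] > iou_threshold]
    alive[suppress] <- FALSE
  }
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep],
       index = keep)
}

#' RoI max pooling
#'
#' Each region of interest is scaled onto the feature map by
#' `spatial_scale`, quantized outward (floor on the near edge, ceiling on
#' the far edge), divided into an `output_size` grid of bins, and
#' max-pooled per bin. Bins that end up empty (degenerate RoIs) yield 0.
#'
#' @param feature_map numeric array `(H, W, C)` (a matrix is treated as
#'   `C = 1`).
#' @param rois box matrix in image coordinates.
#' @param output_size integer `(rows, cols)` of the pooled grid.
#' @param spatial_scale feature-map cells per image pixel (1/stride).
#' @return numeric array `(n_roi, rows, cols, C)`.
#' @export
#' @examples
#' fm <- matrix(1:16, 4, 4, byrow = TRUE)
#' roiPool(fm, c(0, 0, 4, 4), c(2, 2))[1, , , 1]
roiPool <- function(feature_map, rois, output_size = c(2, 2),
                    spatial_scale = 1) {
  if (is.matrix(feature_map))
    feature_map <- array(feature_map, c(dim(feature_map), 1))
  H <- dim(feature_map)[1]; W <- dim(feature_map)[2]
  C <- dim(feature_map)[3]
  rois <- boxMatrix(if (is.numeric(rois) && is.null(dim(rois)))
    matrix(rois, ncol = 4, byrow = TRUE) else rois)
  oh <- output_size[1]; ow <- output_size[2]
  out <- array(0, c(nrow(rois), oh, ow, C))
  for (r in seq_len(nrow(rois))) {
    x0 <- max(0, floor(rois[r, 1] * spatial_scale))
    y0 <- max(0, floor(rois[r, 2] * spatial_scale))
    x1 <- min(W, ceiling(rois[r, 3] * spatial_scale))
    y1 <- min(H, ceiling(rois[r, 4] * spatial_scale))
    for (by in seq_len(oh)) {
      ry0 <- floor(y0 + (y1 - y0) * (by - 1) / oh)
      ry1 <- ceiling(y0 + (y1 - y0) * by / oh)
      for (bx in seq_len(ow)) {
        rx0 <- floor(x0 + (x1 - x0) * (bx - 1) / ow)
        rx1 <- ceiling(x0 + (x1 - x0) * bx / ow)
        if (ry1 > ry0 && rx1 > rx0) {
          block <- feature_map[(ry0 + 1):ry1, (rx0 + 1):rx1, , drop = FALSE]
          out[r, by, bx, ] <- apply(block, 3, max)
        }
      }
    }
  }
  out
}

#' Smooth-L1 (Huber) penalty
#'
#' `0.5 x^2 / beta` for `|x| < beta`, else `|x| - beta / 2`.
#'
#' @param x numeric errors.
#' @param beta transition point.
#' @return elementwise penalties.
#' @export
smoothL1 <- function(x, beta = 1) {
  ifelse(abs(x) < beta, 0.5 * x^2 / beta, abs(x) - beta / 2)
}

#' Multi-task detection loss
#'
#' Classification cross-entropy plus `lambda_loc` times the localization
#' penalty: `CE` is the mean over all samples of the softmax negative
#' log-likelihood of the target class; the localization term is the mean
#' over positive samples of the summed per-coordinate [smoothL1()] error,
#' and contributes 0 when there are no positives.
#'
#' @param cls_scores numeric matrix of class logits, one row per sample.
#' @param cls_targets integer class indices (1-based), one per sample.
#' @param box_preds,box_targets matrices of box-regression coefficients,
#'   one row per sample.
#' @param positive_mask logical vector marking samples whose localization
#'   error counts.
#' @param lambda_loc weight of the localization term.
#' @param beta smooth-L1 transition point.
#' @return scalar loss with attributes `cls` and `loc` (the two terms).
#' @export
multitaskLoss <- function(cls_scores, cls_targets, box_preds, box_targets,
                          positive_mask, lambda_loc = 1, beta = 1) {
  cls_scores <- as.matrix(cls_scores)
  n <- nrow(cls_scores)
  if (n == 0L) stop("multitaskLoss requires at least one sample")
  z <- cls_scores - apply(cls_scores, 1, max)
  logp <- z - log(rowSums(exp(z)))
  ce <- -mean(logp[cbind(seq_len(n), cls_targets)])
  npos <- sum(positive_mask)
  loc <- if (npos > 0) {
    err <- as.matrix(box_preds)[positive_mask, , drop = FALSE] -
           as.matrix(box_targets)[positive_mask, , drop = FALSE]
    sum(smoothL1(err, beta)) / npos
  } else 0
  structure(ce + lambda_loc * loc, cls = ce, loc = loc)
}

#' Rasterize filtered detections into a labeled mask (detection filtering)
#'
#' Applies the detection-filtering model — a detection survives when its
#' score reaches `score_threshold`, the RGI over the disc at its center
#' (radius half the box's smaller side) reaches `rgi_threshold`, and its
#' area lies within `area_range` times the median detected area — and then
#' sets every pixel inside a surviving box to 1. Overlapping boxes count
#' once: the mask is the set union.
#'
#' @param image_shape integer `(height, width)`.
#' @param detections detection data.frame, boxes clipped to the image.
#' @param image optional image used for the RGI criterion; when `NULL` the
#'   RGI filter is skipped.
#' @param score_threshold minimum detector score.
#' @param rgi_threshold minimum center-disc RGI.
#' @param area_range multiplicative band around the median box area;
#'   `NULL` disables the area filter.
#' @return binary mask matrix; attribute `kept` gives the surviving rows.
#' @export
labelCells <- function(image_shape, detections, image = NULL,
                       score_threshold = 0.5, rgi_threshold = 0,
                       area_range = c(0.25, 4)) {
  mask <- matrix(0, image_shape[1], image_shape[2])
  if (nrow(detections) == 0L) {
    attr(mask, "kept") <- integer(0)
    return(mask)
  }
  bm <- boxMatrix(detections)
  keep <- detections$score >= score_threshold
  if (!is.null(area_range) && any(keep)) {
    area <- (bm[, 3] - bm[, 1]) * (bm[, 4] - bm[, 2])
    med <- median(area[keep])
    keep <- keep & area >= area_range[1] * med & area <= area_range[2] * med
  }
  if (!is.null(image)) {
    for (i in which(keep)) {
      cx <- (bm[i, 1] + bm[i, 3]) / 2; cy <- (bm[i, 2] + bm[i, 4]) / 2
      rad <- max(1, min(bm[i, 3] - bm[i, 1], bm[i, 4] - bm[i, 2]) / 2)
      if (radialGradientIndex(image, c(cx, cy), rad) < rgi_threshold)
        keep[i] <- FALSE
    }
  }
  for (i in which(keep)) {
    rows <- (floor(bm[i, 2]) + 1):ceiling(bm[i, 4])
    cols <- (floor(bm[i, 1]) + 1):ceiling(bm[i, 3])
    rows <- rows[rows >= 1 & rows <= image_shape[1]]
    cols <- cols[cols >= 1 & cols <= image_shape[2]]
    mask[rows, cols] <- 1
  }
  attr(mask, "kept") <- which(keep)
  mask
}
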