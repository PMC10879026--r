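## Post-detection operations applied to raw detections before final
## output: scoring each region by detector confidence, radial gradient
## index and box-counting fractal dimension; ranking regions by a weighted
## combination; and filtering out detections whose center disc lacks the
## radial blob signature of a cell.

#' Box-counting (Minkowski-Bouligand) fractal dimension
#'
#' The patch is padded to the next power-of-two square, covered with boxes
#' of dyadic side `s = 1, 2, ..., size/2`, and the occupied-box counts
#' `N(s)` regressed as `log N(s) ~ log(1/s)`; the least-squares slope,
#' clamped to \[0, 2\], is the dimension estimate. Filled regions score
#' close to 2, curves close to 1, isolated points 0 — which makes the
#' score a cheap plausibility feature separating solid cell-like regions
#' from thin artifacts.
#'
#' @param mask_patch binary matrix with at least one foreground pixel.
#' @return dimension estimate in \[0, 2\].
#' @export
#' @examples
#' fractalDimension(matrix(1, 64, 64))  # ~2
fractalDimension <- function(mask_patch) {
  if (sum(mask_patch) == 0) stop("empty patch has no fractal dimension")
  m <- nrow(mask_patch); n <- ncol(mask_patch)
  size <- 2^ceiling(log2(max(m, n, 2)))
  pad <- matrix(0, size, size)
  pad[1:m, 1:n] <- mask_patch
  sizes <- 2^(0:(log2(size) - 1))
  counts <- vapply(sizes, function(s) {
    nb <- size / s
    occ <- 0L
    for (bi in seq_len(nb)) {
      rows <- ((bi - 1) * s + 1):(bi * s)
      rs <- pad[rows, , drop = FALSE]
      ## occupied boxes along this band: any foreground per column block
      colblocks <- colSums(rs) > 0
      occ <- occ + sum(vapply(seq_len(nb), function(bj) {
        any(colblocks[((bj - 1) * s + 1):(bj * s)])
      }, logical(1)))
    }
    occ
  }, numeric(1))
  if (length(unique(counts)) == 1L) return(0)
  slope <- coef(lm(log(counts) ~ log(1 / sizes)))[2]
  min(max(as.numeric(slope), 0), 2)
}

#' Score and rank detected regions
#'
#' For every detection computes three components: the detector score, the
#' RGI of the disc at the box center (radius half the smaller side), and
#' the box-counting dimension of the Otsu-thresholded patch. Components
#' are min-max normalized across the detection set (a constant component
#' maps to 0.5) and combined as a weighted sum; the result is returned
#' ranked, stable on ties.
#'
#' @param image numeric matrix.
#' @param detections detection data.frame with boxes clipped to the image.
#' @param weights named numeric vector with entries `detector`, `rgi`,
#'   `fractal`.
#' @return data.frame with the detection columns plus `rgi`, `fractal`,
#'   `combined` and `rank`, ordered by rank.
#' @export
scoreRegions <- function(image, detections,
                         weights = c(detector = 0.6, rgi = 0.3,
                                     fractal = 0.1)) {
  n <- nrow(detections)
  if (n == 0L) {
    out <- detections
    out$rgi <- numeric(0); out$fractal <- numeric(0)
    out$combined <- numeric(0); out$rank <- integer(0)
    return(out)
  }
  bm <- boxMatrix(detections)
  rgi <- fract <- numeric(n)
  for (i in seq_len(n)) {
    cx <- (bm[i, 1] + bm[i, 3]) / 2; cy <- (bm[i, 2] + bm[i, 4]) / 2
    rad <- max(1, min(bm[i, 3] - bm[i, 1], bm[i, 4] - bm[i, 2]) / 2)
    rgi[i] <- radialGradientIndex(image, c(cx, cy), rad)
    rows <- max(1, floor(bm[i, 2]) + 1):min(nrow(image), ceiling(bm[i, 4]))
    cols <- max(1, floor(bm[i, 1]) + 1):min(ncol(image), ceiling(bm[i, 3]))
    patch <- image[rows, cols, drop = FALSE]
    pb <- if (min(patch) < max(patch)) {
      (patch <= selectThreshold(patch)) * 1
    } else matrix(1, nrow(patch), ncol(patch))
    fract[i] <- if (sum(pb) > 0) fractalDimension(pb) else 0
  }
  mm <- function(v) {
    if (max(v) == min(v)) rep(0.5, length(v)) else
      (v - min(v)) / (max(v) - min(v))
  }
  combined <- weights["detector"] * mm(detections$score) +
    weights["rgi"] * mm(rgi) + weights["fractal"] * mm(fract)
  out <- detections
  out$rgi <- rgi; out$fractal <- fract; out$combined <- as.numeric(combined)
  ord <- order(-out$combined)                  # stable on ties
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Filter detections by radial gradient index
#'
#' Keeps detections whose center-disc RGI (radius half the box's smaller
#' side) is at least `rgi_threshold`; input order is preserved. The
#' operation is idempotent and its output is always a subset of its
#' input.
#'
#' @param image numeric matrix.
#' @param detections detection data.frame with boxes clipped to the image.
#' @param rgi_threshold minimum RGI in \[-1, 1\].
#' @return the surviving rows of `detections`.
#' @export
rgiRegionFilter <- function(image, detections, rgi_threshold = 0) {
  if (nrow(detections) == 0L) return(detections)
  bm <- boxMatrix(detections)
  keep <- vapply(seq_len(nrow(bm)), function(i) {
    cx <- (bm[i, 1] + bm[i, 3]) / 2; cy <- (bm[i, 2] + bm[i, 4]) / 2
    rad <- max(1, min(bm[i, 3] - bm[i, 1], bm[i, 4] - bm[i, 2]) / 2)
    radialGradientIndex(image, c(cx, cy), rad) >= rgi_threshold
  }, logical(1))
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
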