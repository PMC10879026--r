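## Threshold-based segmentation with morphological refinement. The chain is:
## pick a threshold T, split the image into background B (intensity > T)
## and foreground F (intensity <= T), erode B and dilate F over a
## structuring element, and combine: a pixel belongs to the result R when
## the dilated foreground covers it and the eroded background does not.
## Cells are assumed dark on a bright background; use `polarity = "bright"`
## in segmentCells() for the opposite convention.

#' Structuring element for morphological operations
#'
#' A structuring element is the set of `(p, q)` offsets over which erosion
#' takes a minimum and dilation a maximum. It must contain the origin.
#'
#' @param shape `"square"` (default) or `"cross"`.
#' @param size odd side length in pixels.
#' @return integer matrix with columns `p` (row offset) and `q` (column
#'   offset).
#' @export
structuringElement <- function(shape = c("square", "cross"), size = 3) {
  shape <- match.arg(shape)
  if (size %% 2 != 1 || size < 1) stop("size must be odd and positive")
  r <- (size - 1) / 2
  off <- expand.grid(p = -r:r, q = -r:r)
  if (shape == "cross") off <- off[off$p == 0 | off$q == 0, ]
  as.matrix(off)
}

#' Select an intensity threshold
#'
#' The default method is Otsu's criterion (maximizing between-class
#' variance over a 256-bin histogram); `method = "fixed"` passes `value`
#' through unchanged.
#'
#' @param image numeric matrix in \[0, 1\]; must contain at least two
#'   distinct values for Otsu.
#' @param method `"otsu"` or `"fixed"`.
#' @param value the threshold when `method = "fixed"`.
#' @param levels number of histogram bins for Otsu.
#' @return scalar threshold in image units.
#' @export
selectThreshold <- function(image, method = c("otsu", "fixed"), value = 0.5,
                            levels = 256) {
  method <- match.arg(method)
  if (method == "fixed") return(value)
  if (min(image) == max(image))
    stop("cannot select an Otsu threshold on a constant image")
  as.numeric(EBImage::otsu(EBImage::Image(image), range = c(0, 1),
                           levels = levels))
}

#' Split an image into background and foreground masks
#'
#' Background `B` holds pixels with intensity strictly above `T`;
#' foreground `F` holds pixels with intensity at or below `T` (the boundary
#' value is foreground). The two masks partition the grid: `B + F = 1`
#' everywhere.
#'
#' @param image numeric matrix.
#' @param T scalar threshold.
#' @return list with binary matrices `B` and `F`.
#' @export
thresholdSplit <- function(image, T) {
  if (!is.finite(T)) stop("threshold must be finite")
  B <- (image > T) * 1
  F <- (image <= T) * 1
  list(B = B, F = F)
}

## shared min/max-over-offsets engine; out-of-bounds neighbors count as 0
morphOp <- function(mask, S, op) {
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(if (op == "min") 1 else 0, m, n)
  for (k in seq_len(nrow(S))) {
    p <- S[k, 1]; q <- S[k, 2]
    shifted <- matrix(0, m, n)  # out-of-bounds neighbors are 0
    ri <- max(1, 1 - p):min(m, m - p)
    cj <- max(1, 1 - q):min(n, n - q)
    shifted[ri, cj] <- mask[ri + p, cj + q]
    out <- if (op == "min") pmin(out, shifted) else pmax(out, shifted)
  }
  out
}

#' Morphological erosion and dilation
#'
#' Erosion takes the minimum of the mask over the structuring element
#' (`out(i,j) = min_{(p,q) in S} mask(i+p, j+q)`), dilation the maximum.
#' Neighbors falling outside the image are treated as 0 in both operations,
#' so erosion eats a border frame and dilation cannot grow from outside.
#'
#' @param mask binary matrix (values 0/1).
#' @param S structuring element from [structuringElement()].
#' @return binary matrix of the same shape.
#' @export
erodeMask <- function(mask, S = structuringElement()) {
  stopifnot(all(mask %in% c(0, 1)))
  morphOp(mask, S, "min")
}

#' @rdname erodeMask
#' @export
dilateMask <- function(mask, S = structuringElement()) {
  stopifnot(all(mask %in% c(0, 1)))
  morphOp(mask, S, "max")
}

#' Combine dilated foreground and eroded background
#'
#' The segmentation result is `R(i,j) = 1` exactly where the dilated
#' foreground is 1 and the eroded background is 0, else 0.
#'
#' @param F_dilated dilated foreground mask.
#' @param B_eroded eroded background mask.
#' @return binary result mask `R`.
#' @export
combineMasks <- function(F_dilated, B_eroded) {
  if (!all(dim(F_dilated) == dim(B_eroded))) stop("mask shape mismatch")
  (F_dilated == 1 & B_eroded == 0) * 1
}

#' Label connected components of a binary mask
#'
#' 8-connectivity labeling by iterative minimum-label propagation; labels
#' are renumbered 1..K in raster order of each component's first pixel.
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(seq_len(m * n), m, n)
  lab[mask == 0] <- 0L
  offs <- structuringElement("square", 3)
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  repeat {
    nxt <- lab
    for (k in seq_len(nrow(offs))) {
      p <- offs[k, 1]; q <- offs[k, 2]
      ri <- max(1, 1 - p):min(m, m - p)
      cj <- max(1, 1 - q):min(n, n - q)
      nb <- lab[ri + p, cj + q]
      cur <- nxt[ri, cj]
      take <- nb > 0 & cur > 0 & nb < cur
      cur[take] <- nb[take]
      nxt[ri, cj] <- cur
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- unique(lab[lab > 0])
  relab <- match(lab, ids)
  relab[is.na(relab)] <- 0L
  out <- matrix(as.integer(relab), m, n)
  out
}

#' Count cells in a segmentation mask
#'
#' Connected components (8-connectivity) with area below `min_area` are
#' discarded as noise; the survivors are returned with tight bounding
#' boxes, areas and centroids.
#'
#' @param R binary result mask.
#' @param min_area smallest component area kept, in pixels.
#' @return list with `count` and a data.frame `regions`
#'   (`label, x0, y0, x1, y1, area, cx, cy`).
#' @export
countCells <- function(R, min_area = 30) {
  lab <- labelComponents(R)
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0L) {
    return(list(count = 0L, regions = data.frame(
      label = integer(0), x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
      y1 = numeric(0), area = integer(0), cx = numeric(0), cy = numeric(0))))
  }
  rows <- lapply(labs, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) < min_area) return(NULL)
    data.frame(label = k, x0 = min(w[, 2]) - 1, y0 = min(w[, 1]) - 1,
               x1 = max(w[, 2]), y1 = max(w[, 1]), area = nrow(w),
               cx = mean(w[, 2]) - 0.5, cy = mean(w[, 1]) - 0.5)
  })
  regions <- do.call(rbind, rows)
  if (is.null(regions)) regions <- data.frame(
    label = integer(0), x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
    y1 = numeric(0), area = integer(0), cx = numeric(0), cy = numeric(0))
  regions$label <- seq_len(nrow(regions))
  list(count = nrow(regions), regions = regions)
}

#' Full threshold-and-morphology segmentation pipeline
#'
#' Runs the complete chain: optional bilateral pre-filtering, threshold
#' selection, background/foreground split, erosion of the background and
#' dilation of the foreground, combination into the result mask, and
#' connected-component counting. `mode = "combine"` merges the masks as
#' described above; `mode = "opening"` instead applies a conventional
#' morphological opening (erosion then dilation) to the foreground.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param threshold `"otsu"` or a numeric value.
#' @param S structuring element.
#' @param min_area smallest cell area kept.
#' @param polarity `"dark"` (cells darker than background, default) or
#'   `"bright"` (image is inverted first).
#' @param filter_params optional [filterParams()] list; when supplied the
#'   image is bilateral-filtered first.
#' @param mode `"combine"` or `"opening"` (see Details).
#' @return list with `count`, `regions`, the result `mask`, and the
#'   `threshold` used.
#' @export
segmentCells <- function(image, threshold = "otsu",
                         S = structuringElement(), min_area = 30,
                         polarity = c("dark", "bright"),
                         filter_params = NULL,
                         mode = c("combine", "opening")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  img <- if (polarity == "bright") 1 - image else image
  if (!is.null(filter_params)) img <- iterateFilter(img, filter_params)
  T <- if (identical(threshold, "otsu")) selectThreshold(img) else
    as.numeric(threshold)
  bf <- thresholdSplit(img, T)
  R <- if (mode == "combine") {
    combineMasks(dilateMask(bf$F, S), erodeMask(bf$B, S))
  } else {
    dilateMask(erodeMask(bf$F, S), S)
  }
  res <- countCells(R, min_area)
  list(count = res$count, regions = res$regions, mask = R, threshold = T)
}
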