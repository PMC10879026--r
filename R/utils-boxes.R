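## Box utilities shared across the detector, evaluation and post-processing
## stages. All boxes are 0-based half-open (x0, y0, x1, y1); see the package
## help page for the coordinate conventions.

#' Construct a detection table
#'
#' Builds the canonical detection `data.frame` used throughout the package:
#' one row per box with columns `x0, y0, x1, y1, score, label`.
#'
#' @param boxes numeric matrix or data.frame with four columns
#'   `(x0, y0, x1, y1)`.
#' @param score numeric vector of foreground scores in \[0, 1\], recycled.
#' @param label character vector of class tags, recycled. Default `"rbc"`.
#' @return data.frame with columns `x0, y0, x1, y1, score, label`.
#' @export
#' @examples
#' detectionTable(matrix(c(0, 0, 10, 10), 1), score = 0.9)
detectionTable <- function(boxes, score = 1, label = "rbc") {
  boxes <- as.matrix(boxes)
  if (length(boxes) == 0L) {
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), score = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (ncol(boxes) < 4L) stop("boxes must have four columns (x0, y0, x1, y1)")
  data.frame(x0 = boxes[, 1], y0 = boxes[, 2], x1 = boxes[, 3],
             y1 = boxes[, 4], score = rep_len(score, nrow(boxes)),
             label = rep_len(label, nrow(boxes)), stringsAsFactors = FALSE)
}

boxMatrix <- function(det) {
  if (is.data.frame(det)) {
    as.matrix(det[, c("x0", "y0", "x1", "y1"), drop = FALSE])
  } else {
    m <- as.matrix(det)
    if (length(m) == 0L) m <- matrix(numeric(0), 0, 4)
    m
  }
}

#' Pairwise intersection-over-union of two box sets
#'
#' IoU is computed on half-open boxes, so a box's area is
#' `(x1-x0)*(y1-y0)`. Degenerate (zero-area) boxes have IoU 0 against
#' everything, including themselves.
#'
#' @param a,b box matrices or detection data.frames (see [detectionTable()]).
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values in \[0, 1\].
#' @export
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
boxIoU <- function(a, b) {
  a <- boxMatrix(if (is.numeric(a) && is.null(dim(a))) matrix(a, ncol = 4, byrow = TRUE) else a)
  b <- boxMatrix(if (is.numeric(b) && is.null(dim(b))) matrix(b, ncol = 4, byrow = TRUE) else b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), na, nb))
  ix0 <- outer(a[, 1], b[, 1], pmax)
  iy0 <- outer(a[, 2], b[, 2], pmax)
  ix1 <- outer(a[, 3], b[, 3], pmin)
  iy1 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  areaA <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  areaB <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(areaA, areaB, `+`) - inter
  iou <- ifelse(un > 0, inter / un, 0)
  matrix(iou, na, nb)
}

#' Clip boxes to image bounds
#'
#' Coordinates are clamped to `[0, width]` horizontally and `[0, height]`
#' vertically.
#'
#' @param boxes box matrix or detection data.frame.
#' @param image_shape integer `(height, width)` in pixels.
#' @return object of the same class with clipped coordinates.
#' @export
clipBoxes <- function(boxes, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  m <- boxMatrix(boxes)
  m[, 1] <- pmin(pmax(m[, 1], 0), w)
  m[, 3] <- pmin(pmax(m[, 3], 0), w)
  m[, 2] <- pmin(pmax(m[, 2], 0), h)
  m[, 4] <- pmin(pmax(m[, 4], 0), h)
  if (is.data.frame(boxes)) {
    boxes[, c("x0", "y0", "x1", "y1")] <- m
    boxes
  } else m
}

#' Read and write detection/annotation CSV files
#'
#' The on-disk format is a plain CSV with header
#' `image,x0,y0,x1,y1,score,label` (ground-truth files may omit `score`,
#' which then defaults to 1).
#'
#' @param path file path.
#' @param det detection data.frame; an `image` column is added when missing.
#' @param image image identifier written alongside each box.
#' @return `readBoxesCSV` returns a detection data.frame (with an `image`
#'   column); `writeBoxesCSV` returns `path` invisibly.
#' @export
readBoxesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(df))) {
    stop("box CSV must contain columns x0, y0, x1, y1")
  }
  if (is.null(df$score)) df$score <- 1
  if (is.null(df$label)) df$label <- "rbc"
  if (is.null(df$image)) df$image <- ""
  df[, c("image", "x0", "y0", "x1", "y1", "score", "label")]
}

#' @rdname readBoxesCSV
#' @export
writeBoxesCSV <- function(det, path, image = "") {
  if (is.null(det$image)) det <- cbind(image = rep(image, nrow(det)), det)
  write.csv(det, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## run code under a temporary RNG state so exported operations with a `seed`
## argument are reproducible without clobbering the caller's stream
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
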