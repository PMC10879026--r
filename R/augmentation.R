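## Training-set augmentation: random affine transforms (rotation, shift,
## shear, zoom, horizontal flip) applied jointly to an image and its
## ground-truth boxes. Parameter names and defaults follow the common
## image-augmentation convention: rotation in degrees, shifts as fractions
## of the image size, zoom sampled in 1 +/- zoom_range, plus an intensity
## rescale factor for integer-coded input (1/255 maps 8-bit values onto
## [0, 1]; images already normalized use rescale = 1).

#' Augmentation configuration
#'
#' @param rescale multiplicative intensity factor applied after warping
#'   (use `1/255` for raw 8-bit input; default 1 for normalized images).
#' @param rotation_range maximum absolute rotation in degrees.
#' @param width_shift maximum horizontal shift as a fraction of width.
#' @param height_shift maximum vertical shift as a fraction of height.
#' @param shear_range maximum absolute shear in radians.
#' @param zoom_range zoom factor sampled uniformly in
#'   `[1 - zoom_range, 1 + zoom_range]`.
#' @param horizontal_flip flip horizontally with probability 1/2?
#' @param fill_mode edge policy for resampling: `"nearest"`, `"constant"`
#'   or `"reflect"`.
#' @return a validated list of class `AugmentConfig`.
#' @export
augmentConfig <- function(rescale = 1, rotation_range = 0.2,
                          width_shift = 0.2, height_shift = 0.1,
                          shear_range = 0.1, zoom_range = 0.5,
                          horizontal_flip = TRUE,
                          fill_mode = c("nearest", "constant", "reflect")) {
  fill_mode <- match.arg(fill_mode)
  if (rescale <= 0) stop("rescale must be > 0")
  rng <- c(rotation_range, width_shift, height_shift, shear_range,
           zoom_range)
  if (any(rng < 0)) stop("augmentation ranges must be >= 0")
  structure(list(rescale = rescale, rotation_range = rotation_range,
                 width_shift = width_shift, height_shift = height_shift,
                 shear_range = shear_range, zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 fill_mode = fill_mode),
            class = "AugmentConfig")
}

## build a 3x3 homogeneous affine matrix from components, centered on the
## image center (cx, cy) in 0-based pixel coordinates
composeAffine <- function(angle_deg, shift_x, shift_y, shear, zoom, flip,
                          cx, cy) {
  rad <- angle_deg * pi / 180
  R <- matrix(c(cos(rad), sin(rad), 0, -sin(rad), cos(rad), 0, 0, 0, 1), 3)
  Sh <- matrix(c(1, 0, 0, -sin(shear), cos(shear), 0, 0, 0, 1), 3)
  Z <- diag(c(zoom, zoom, 1))
  Fl <- diag(c(if (flip) -1 else 1, 1, 1))
  C <- diag(3); C[1:2, 3] <- c(cx, cy)
  Ci <- diag(3); Ci[1:2, 3] <- c(-cx, -cy)
  Tr <- diag(3); Tr[1:2, 3] <- c(shift_x, shift_y)
  Tr %*% C %*% R %*% Sh %*% Z %*% Fl %*% Ci
}

#' Sample a random affine transform
#'
#' Draws rotation, shifts, shear, zoom and flip uniformly from the ranges
#' in `config` and composes them into a single affine map about the image
#' center. With all ranges zero and flipping disabled the result is the
#' exact identity.
#'
#' @param config an [augmentConfig()] list.
#' @param image_shape integer `(height, width)`.
#' @param seed optional integer seed.
#' @return list of class `AffineTransform` with the 3x3 `matrix`, the
#'   component draws, and the `rescale` and `fill_mode` carried over from
#'   the config.
#' @export
sampleTransform <- function(config, image_shape, seed = NULL) {
  withSeed(seed, {
    ang <- if (config$rotation_range > 0)
      runif(1, -config$rotation_range, config$rotation_range) else 0
    sx <- if (config$width_shift > 0)
      runif(1, -config$width_shift, config$width_shift) * image_shape[2] else 0
    sy <- if (config$height_shift > 0)
      runif(1, -config$height_shift, config$height_shift) * image_shape[1] else 0
    sh <- if (config$shear_range > 0)
      runif(1, -config$shear_range, config$shear_range) else 0
    zm <- if (config$zoom_range > 0)
      runif(1, 1 - config$zoom_range, 1 + config$zoom_range) else 1
    fl <- config$horizontal_flip && runif(1) < 0.5
    affineTransform(composeAffine(ang, sx, sy, sh, zm, fl,
                                  image_shape[2] / 2, image_shape[1] / 2),
                    rescale = config$rescale, fill_mode = config$fill_mode,
                    components = list(angle = ang, shift_x = sx,
                                      shift_y = sy, shear = sh, zoom = zm,
                                      flip = fl))
  })
}

#' @describeIn sampleTransform wrap a 3x3 matrix as an `AffineTransform`.
#' @param matrix 3x3 homogeneous affine matrix mapping input `(x, y, 1)` to
#'   output coordinates.
#' @param rescale intensity factor applied with the transform.
#' @param fill_mode edge policy.
#' @param components optional list of the sampled components.
#' @export
affineTransform <- function(matrix = diag(3), rescale = 1,
                            fill_mode = "nearest", components = list()) {
  structure(list(matrix = matrix, rescale = rescale, fill_mode = fill_mode,
                 components = components), class = "AffineTransform")
}

#' Apply an affine transform to an image and its boxes
#'
#' The image is warped by inverse mapping with bilinear resampling and the
#' configured fill policy. Each box is mapped by transforming its four
#' corners and taking the axis-aligned hull, then clipping to the image;
#' boxes that collapse to zero area are dropped. An exact-identity
#' transform reproduces the input bit for bit (up to the `rescale`
#' factor).
#'
#' @param image numeric matrix.
#' @param boxes detection data.frame (may be empty).
#' @param t an `AffineTransform` (see [sampleTransform()]).
#' @param fill_mode override of the transform's fill policy.
#' @return list with warped `image` and transformed `boxes`.
#' @export
applyTransform <- function(image, boxes = detectionTable(matrix(numeric(0), 0, 4)),
                           t, fill_mode = NULL) {
  A <- t$matrix
  if (abs(det(A)) < 1e-12) stop("singular affine transform")
  fm <- if (is.null(fill_mode)) t$fill_mode else fill_mode
  m <- nrow(image); n <- ncol(image)
  Ainv <- solve(A)
  ## output pixel centers in 0-based coordinates
  xc <- rep(seq_len(n) - 0.5, each = m)
  yc <- rep(seq_len(m) - 0.5, times = n)
  src <- Ainv %*% rbind(xc, yc, 1)
  ## convert 0-based centers to 1-based matrix indices: index = coord + 0.5
  vals <- bilinearSample(image, xi = src[1, ] + 0.5, yi = src[2, ] + 0.5,
                         grid = FALSE, fill_mode = fm)
  out <- matrix(vals, m, n) * t$rescale
  newBoxes <- boxes[0, , drop = FALSE]
  if (nrow(boxes) > 0) {
    bm <- boxMatrix(boxes)
    mapped <- lapply(seq_len(nrow(bm)), function(i) {
      b <- bm[i, ]
      corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[1], b[4]),
                       c(b[3], b[4]))
      p <- A %*% rbind(t(corners), 1)
      c(min(p[1, ]), min(p[2, ]), max(p[1, ]), max(p[2, ]))
    })
    nb <- do.call(rbind, mapped)
    nb <- clipBoxes(nb, c(m, n))
    keep <- (nb[, 3] - nb[, 1]) > 0 & (nb[, 4] - nb[, 2]) > 0
    newBoxes <- boxes[keep, , drop = FALSE]
    if (any(keep)) newBoxes[, c("x0", "y0", "x1", "y1")] <-
      nb[keep, , drop = FALSE]
    rownames(newBoxes) <- NULL
  }
  list(image = out, boxes = newBoxes)
}

#' Augment a scene several times
#'
#' Draws `k` transforms from `config` and applies each to the scene's
#' image and boxes.
#'
#' @param scene a [BloodCellScene-class] or a list with `image` and
#'   `boxes`.
#' @param config an [augmentConfig()] list.
#' @param k number of augmented copies.
#' @param seed integer seed.
#' @return list of `k` lists with `image` and `boxes`.
#' @export
augmentScene <- function(scene, config = augmentConfig(), k = 1, seed = 1) {
  img <- if (is(scene, "BloodCellScene")) sceneImage(scene) else scene$image
  bxs <- if (is(scene, "BloodCellScene")) sceneBoxes(scene) else scene$boxes
  withSeed(seed, {
    lapply(seq_len(k), function(i) {
      tr <- sampleTransform(config, dim(img))
      applyTransform(img, bxs, tr)
    })
  })
}
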