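## Reading, writing, normalizing and resizing grayscale images. In memory an
## image is a plain numeric matrix (rows = y, columns = x) with values in
## [0, 1]; see the package help page for coordinate conventions.

LUMA <- c(0.299, 0.587, 0.114)  # ITU-R BT.601 luminance weights

#' Read an image as a normalized grayscale matrix
#'
#' Supports PNG, TIFF and JPEG. RGB input is converted to grayscale with the
#' BT.601 luminance weights (0.299, 0.587, 0.114); an alpha channel is
#' dropped. Integer-coded files are scaled to \[0, 1\] by their codec.
#'
#' @param path path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return numeric matrix with values in \[0, 1\].
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext)
  )
  toGrayscale(arr)
}

#' Convert an image array to a grayscale matrix
#'
#' @param arr matrix (grayscale), or H x W x C array with C = 2 (gray +
#'   alpha), 3 (RGB) or 4 (RGBA).
#' @return numeric matrix; RGB channels are combined with BT.601 weights.
#' @export
toGrayscale <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) != 3L) stop("expected a matrix or 3-d array")
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1])
  if (nc == 2L) return(arr[, , 1])          # gray + alpha
  LUMA[1] * arr[, , 1] + LUMA[2] * arr[, , 2] + LUMA[3] * arr[, , 3]
}

#' Write a grayscale image
#'
#' PNG and JPEG are written 8-bit (values clipped to \[0, 1\]); TIFF is
#' written as 32-bit float and round-trips exactly.
#'
#' @param image numeric matrix.
#' @param path output path; the extension selects the codec.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  clipped <- pmin(pmax(image, 0), 1)
  switch(ext,
    png = png::writePNG(clipped, path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 32,
                                   compression = "none"),
    jpg = , jpeg = jpeg::writeJPEG(clipped, path, quality = 0.95),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write and read 16-bit integer label masks
#'
#' Instance masks (integer labels 0..65535) round-trip losslessly through
#' PNG: the 16-bit label is packed into two 8-bit channels (red = high
#' byte, green = low byte) of an RGB PNG.
#'
#' @param mask integer matrix of labels in 0..65535.
#' @param path PNG path.
#' @return `writeMask` returns `path` invisibly; `readMask` returns the
#'   integer label matrix.
#' @export
writeMask <- function(mask, path) {
  if (max(mask) > 65535 || min(mask) < 0) stop("labels exceed 16-bit range")
  hi <- mask %/% 256
  lo <- mask %% 256
  arr <- array(0, c(nrow(mask), ncol(mask), 3))
  arr[, , 1] <- hi / 255
  arr[, , 2] <- lo / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L) stop("not a packed label mask")
  m <- round(arr[, , 1] * 255) * 256L + round(arr[, , 2] * 255)
  storage.mode(m) <- "integer"
  m
}

#' Min-max normalize an image to \[0, 1\]
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' image maps to all zeros (the 0/0 case is defined away deterministically).
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param image numeric matrix with finite values.
#' @return numeric matrix in \[0, 1\].
#' @export
#' @examples
#' normalizeImage(matrix(c(10, 20, 30), 1))  # 0, 0.5, 1
normalizeImage <- function(image) {
  if (any(!is.finite(image))) stop("image contains non-finite values")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(array(0, dim(image)))
  (image - lo) / (hi - lo)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Pixel-center alignment: output pixel center `(x + 0.5)` maps to input
#' coordinate `(x + 0.5) * n_in / n_out`, so resizing to the original size
#' is an exact identity and output values never overshoot the input range.
#' The default target, 24 x 24, is the working size of the patch
#' classifier head; detection itself runs at full resolution.
#'
#' @param image numeric matrix.
#' @param size integer `(height, width)` target, both positive.
#' @return numeric matrix of dimension `size`.
#' @export
resizeImage <- function(image, size = c(24, 24)) {
  size <- as.integer(size)
  if (any(size <= 0)) stop("target size must be positive")
  m <- nrow(image); n <- ncol(image)
  ## sample coordinates of output pixel centers in input index space (1-based)
  yi <- (seq_len(size[1]) - 0.5) * m / size[1] + 0.5
  xi <- (seq_len(size[2]) - 0.5) * n / size[2] + 0.5
  bilinearSample(image, xi = xi, yi = yi, grid = TRUE, fill_mode = "nearest")
}

## Bilinear sampling at (xi, yi) in 1-based matrix index coordinates
## (yi = row, xi = column). grid = TRUE treats xi/yi as axis vectors and
## returns the outer grid; otherwise they are paired coordinates.
## fill_mode: "nearest" clamps coordinates, "constant" fills with `fill`,
## "reflect" mirrors about the border.
bilinearSample <- function(image, xi, yi, grid = FALSE,
                           fill_mode = c("nearest", "constant", "reflect"),
                           fill = 0) {
  fill_mode <- match.arg(fill_mode)
  m <- nrow(image); n <- ncol(image)
  mapc <- function(v, k) {
    switch(fill_mode,
      nearest = pmin(pmax(v, 1), k),
      reflect = {
        if (k == 1L) rep(1, length(v)) else {
          p <- 2 * (k - 1)
          w <- (v - 1) %% p
          1 + pmin(w, p - w)
        }
      },
      constant = v)
  }
  xm <- mapc(xi, n); ym <- mapc(yi, m)
  x0 <- floor(xm); y0 <- floor(ym)
  fx <- xm - x0; fy <- ym - y0
  ## exactness shortcut: integer coordinates hit pixels exactly
  x0 <- pmin(pmax(x0, 1), n); y0 <- pmin(pmax(y0, 1), m)
  x1 <- pmin(x0 + 1, n); y1 <- pmin(y0 + 1, m)
  if (grid) {
    FX <- matrix(fx, length(yi), length(xi), byrow = TRUE)
    FY <- matrix(fy, length(yi), length(xi))
    g00 <- image[y0, x0, drop = FALSE]; g01 <- image[y0, x1, drop = FALSE]
    g10 <- image[y1, x0, drop = FALSE]; g11 <- image[y1, x1, drop = FALSE]
    out <- (1 - FY) * ((1 - FX) * g00 + FX * g01) +
           FY * ((1 - FX) * g10 + FX * g11)
  } else {
    i00 <- cbind(y0, x0); i01 <- cbind(y0, x1)
    i10 <- cbind(y1, x0); i11 <- cbind(y1, x1)
    out <- (1 - fy) * ((1 - fx) * image[i00] + fx * image[i01]) +
           fy * ((1 - fx) * image[i10] + fx * image[i11])
  }
  if (fill_mode == "constant") {
    bad <- if (grid) {
      outer(yi < 0.5 | yi > m + 0.5, xi < 0.5 | xi > n + 0.5, `|`)
    } else (xi < 0.5 | xi > n + 0.5) | (yi < 0.5 | yi > m + 0.5)
    out[bad] <- fill
  }
  out
}
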