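## Edge-preserving noise reduction: a bilateral filter whose weights combine
## a spatial Gaussian (scale sigma_d) with an intensity-range Gaussian
## (scale sigma_r), applied iteratively, plus the radial gradient index
## (RGI), a blob score reused by the post-detection filtering stage.

#' Bilateral filter parameters
#'
#' @param sigma_d spatial scale in pixels (> 0); controls the spatial
#'   extent of the filter.
#' @param sigma_r intensity-range scale (> 0); controls how strongly
#'   intensity differences suppress a neighbor's weight, and hence how well
#'   edges are preserved.
#' @param window_radius half-width of the square filtering window in
#'   pixels; `NULL` selects `ceiling(3 * sigma_d)`, beyond which the
#'   spatial weight is negligible.
#' @param n_iterations maximum number of filter passes (>= 1).
#' @param convergence_tol stop early when the mean absolute change per
#'   pixel between passes drops below this.
#' @return a validated list of class `FilterParams`.
#' @export
filterParams <- function(sigma_d = 1.5, sigma_r = 0.1, window_radius = NULL,
                         n_iterations = 1, convergence_tol = 1e-4) {
  if (sigma_d <= 0) stop("sigma_d must be > 0")
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  if (is.null(window_radius)) window_radius <- ceiling(3 * sigma_d)
  if (window_radius < 0) stop("window_radius must be >= 0")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r,
                 window_radius = as.integer(window_radius),
                 n_iterations = as.integer(n_iterations),
                 convergence_tol = convergence_tol),
            class = "FilterParams")
}

#' Bilateral weight between two pixels
#'
#' Returns the distance weight `wd = exp(-((i-p)^2 + (j-q)^2) / (2 sigma_d^2))`,
#' the range weight `wr = exp(-(I(i,j) - I(p,q))^2 / (2 sigma_r^2))` and
#' their product `w = wd * wr`. Indices are 1-based matrix indices.
#'
#' @param image numeric matrix.
#' @param i,j row/column of the pixel being filtered.
#' @param p,q row/column of the contributing neighbor.
#' @param params a [filterParams()] list.
#' @return named list with components `wd`, `wr`, `w`.
#' @export
#' @examples
#' img <- matrix(0.5, 3, 3)
#' bilateralWeights(img, 2, 2, 2, 2, filterParams())$w  # 1
bilateralWeights <- function(image, i, j, p, q, params = filterParams()) {
  m <- nrow(image); n <- ncol(image)
  if (any(c(i, p) < 1) || any(c(i, p) > m) || any(c(j, q) < 1) ||
      any(c(j, q) > n)) stop("pixel indices out of bounds")
  wd <- exp(-((i - p)^2 + (j - q)^2) / (2 * params$sigma_d^2))
  wr <- exp(-(image[i, j] - image[p, q])^2 / (2 * params$sigma_r^2))
  list(wd = wd, wr = wr, w = wd * wr)
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the weighted average of its square neighborhood,
#' `I'(i,j) = sum_w w * I(p,q) / W(i,j)`, with weights from
#' [bilateralWeights()] and `W` the per-pixel sum of weights. The
#' neighborhood is the `(2r+1)^2` window (`r = window_radius`), clipped at
#' image borders with `W` adjusting accordingly — no padding is invented.
#' Because the output is a convex combination, it stays within the input's
#' value range; a constant image is a fixed point, and `window_radius = 0`
#' is the identity.
#'
#' @param image numeric matrix with finite values.
#' @param params a [filterParams()] list.
#' @return filtered numeric matrix of the same shape.
#' @export
bilateralFilter <- function(image, params = filterParams()) {
  if (any(!is.finite(image))) stop("image contains non-finite values")
  r <- params$window_radius
  if (r == 0L) return(image)
  m <- nrow(image); n <- ncol(image)
  acc <- matrix(0, m, n); wsum <- matrix(0, m, n)
  inv2sd <- 1 / (2 * params$sigma_d^2)
  inv2sr <- 1 / (2 * params$sigma_r^2)
  ## vectorized over pixels: loop only over the (2r+1)^2 window offsets,
  ## shifting the whole image for each offset
  for (dp in -r:r) {
    ri <- max(1, 1 - dp):min(m, m - dp)     # rows with in-bounds neighbor
    for (dq in -r:r) {
      cj <- max(1, 1 - dq):min(n, n - dq)
      wd <- exp(-(dp * dp + dq * dq) * inv2sd)
      nb <- image[ri + dp, cj + dq, drop = FALSE]
      ce <- image[ri, cj, drop = FALSE]
      w <- wd * exp(-(ce - nb)^2 * inv2sr)
      acc[ri, cj] <- acc[ri, cj] + w * nb
      wsum[ri, cj] <- wsum[ri, cj] + w
    }
  }
  acc / wsum
}

#' Iterated bilateral filtering
#'
#' Applies [bilateralFilter()] repeatedly until `n_iterations` passes have
#' run or the mean absolute per-pixel change falls below
#' `convergence_tol`, whichever comes first.
#'
#' @param image numeric matrix.
#' @param params a [filterParams()] list; `n_iterations` and
#'   `convergence_tol` control the iteration.
#' @return the filtered image, with attribute `iterations` giving the
#'   number of passes actually applied.
#' @export
iterateFilter <- function(image, params = filterParams(n_iterations = 3)) {
  out <- image
  used <- 0L
  for (k in seq_len(params$n_iterations)) {
    nxt <- bilateralFilter(out, params)
    delta <- mean(abs(nxt - out))
    out <- nxt
    used <- k
    if (delta < params$convergence_tol) break
  }
  attr(out, "iterations") <- used
  out
}

#' Radial gradient index of a disc region
#'
#' Scores how strongly local intensity gradients around `center` are
#' radially aligned: the mean, over disc pixels with a nonzero gradient, of
#' the cosine of the angle between the intensity gradient and the outward
#' radial direction. A radially symmetric dark-center blob has all
#' gradients pointing outward, giving +1; a bright-center blob gives -1;
#' structureless texture, or a disc placed well away from any blob (where
#' the field is locally one-sided), gives values near 0 because opposite
#' sides of the disc cancel. Pixels with exactly zero gradient contribute
#' 0; if the disc contains no gradient at all the score is 0.
#'
#' Gradients are central differences in the interior and one-sided at the
#' image border. The pixel at the exact center is excluded (its radial
#' direction is undefined).
#'
#' @param image numeric matrix.
#' @param center `(x, y)` disc center in 0-based pixel coordinates.
#' @param radius disc radius in pixels; the disc must intersect the image.
#' @return RGI score in \[-1, 1\].
#' @export
radialGradientIndex <- function(image, center, radius) {
  m <- nrow(image); n <- ncol(image)
  if (radius <= 0) stop("radius must be positive")
  if (center[1] < -radius || center[1] > n + radius ||
      center[2] < -radius || center[2] > m + radius)
    stop("disc does not intersect the image")
  gx <- matrix(0, m, n); gy <- matrix(0, m, n)
  if (n >= 3) gx[, 2:(n - 1)] <- (image[, 3:n] - image[, 1:(n - 2)]) / 2
  if (n >= 2) {
    gx[, 1] <- image[, 2] - image[, 1]
    gx[, n] <- image[, n] - image[, n - 1]
  }
  if (m >= 3) gy[2:(m - 1), ] <- (image[3:m, ] - image[1:(m - 2), ]) / 2
  if (m >= 2) {
    gy[1, ] <- image[2, ] - image[1, ]
    gy[m, ] <- image[m, ] - image[m - 1, ]
  }
  px <- matrix(seq_len(n) - 0.5, m, n, byrow = TRUE) - center[1]
  py <- matrix(seq_len(m) - 0.5, m, n) - center[2]
  rr <- sqrt(px * px + py * py)
  disc <- rr <= radius & rr > 1e-9
  if (!any(disc)) return(0)
  gmag <- sqrt(gx[disc]^2 + gy[disc]^2)
  if (all(gmag == 0)) return(0)
  ## cos(angle between gradient and outward radial) = (g . u_radial) / |g|
  radialDot <- (gx[disc] * px[disc] + gy[disc] * py[disc]) / rr[disc]
  mean(ifelse(gmag > 0, radialDot / gmag, 0))
}
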