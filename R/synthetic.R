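## Synthetic blood-smear scenes with exact ground truth. The generator
## emulates the features that make smear images hard: roughly circular to
## elliptical cells of varying size and intensity, touching/overlapping
## clusters, a slow background illumination gradient, and additive Gaussian
## plus multiplicative speckle noise. Every scene carries its instance mask
## and tight bounding boxes, so each pipeline stage can be tested against
## known truth.

#' Render one elliptical cell onto a canvas
#'
#' The cell support is the ellipse with the given semi-axes; intensity moves
#' from the canvas value to `intensity` with a raised-cosine edge profile
#' over the outer `edge_width` fraction of the normalized elliptic radius,
#' so cell borders are smooth rather than aliased. Pixels outside the
#' ellipse are untouched.
#'
#' @param canvas numeric matrix.
#' @param center `(x, y)` center in 0-based pixel coordinates; must lie
#'   inside the canvas.
#' @param radii `(a, b)` semi-axes in pixels, both positive.
#' @param orientation rotation of the major axis in radians.
#' @param intensity target intensity of the cell interior.
#' @param edge_width fraction of the normalized radius used for the soft
#'   edge (0 gives a hard disk).
#' @return the updated canvas.
#' @export
renderCell <- function(canvas, center, radii, orientation = 0,
                       intensity = 0.35, edge_width = 0.15) {
  if (any(radii <= 0)) stop("radii must be positive")
  m <- nrow(canvas); n <- ncol(canvas)
  if (center[1] < 0 || center[1] > n || center[2] < 0 || center[2] > m)
    stop("center must lie inside the canvas")
  rho <- ellipticRadius(m, n, center, radii, orientation)
  w <- cellProfile(rho, edge_width)
  canvas + w * (intensity - canvas)
}

## normalized elliptic radius of every pixel center: 1 on the ellipse border
ellipticRadius <- function(m, n, center, radii, orientation) {
  x <- matrix(seq_len(n) - 0.5, m, n, byrow = TRUE) - center[1]
  y <- matrix(seq_len(m) - 0.5, m, n) - center[2]
  ca <- cos(orientation); sa <- sin(orientation)
  u <- (ca * x + sa * y) / radii[1]
  v <- (-sa * x + ca * y) / radii[2]
  sqrt(u * u + v * v)
}

## raised-cosine membership: 1 inside, 0 outside, smooth over the edge band
cellProfile <- function(rho, edge_width) {
  if (edge_width <= 0) return((rho <= 1) * 1)
  w <- array(0, dim(rho))
  w[rho <= 1 - edge_width] <- 1
  band <- rho > 1 - edge_width & rho < 1
  w[band] <- 0.5 * (1 + cos(pi * (rho[band] - (1 - edge_width)) / edge_width))
  w
}

#' Add Gaussian and speckle noise to a normalized image
#'
#' The noise model is `out = clip(in * (1 + speckle * s) + g, 0, 1)` with
#' `s, g` standard normal fields scaled by `speckle_strength` and
#' `noise_sigma`. Zero noise returns the input unchanged, bit for bit.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param noise_sigma additive Gaussian standard deviation, >= 0.
#' @param speckle_strength multiplicative speckle amplitude, >= 0.
#' @param seed optional integer seed for a reproducible noise field.
#' @return noisy image clipped to \[0, 1\].
#' @export
addNoise <- function(image, noise_sigma = 0.02, speckle_strength = 0.05,
                     seed = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (speckle_strength < 0) stop("speckle_strength must be >= 0")
  if (noise_sigma == 0 && speckle_strength == 0) return(image)
  withSeed(seed, {
    out <- image
    if (speckle_strength > 0) {
      out <- out * (1 + speckle_strength * array(rnorm(length(image)),
                                                 dim(image)))
    }
    if (noise_sigma > 0) {
      out <- out + array(rnorm(length(image), sd = noise_sigma), dim(image))
    }
    pmin(pmax(out, 0), 1)
  })
}

#' Generate a synthetic blood-smear scene
#'
#' Places `n_cells` ellipses on a background with an optional illumination
#' gradient, renders them with soft edges, applies the noise model, and
#' returns the image together with its exact ground truth. A target
#' fraction `overlap_fraction` of cells is attached to an already placed
#' cell at a center distance below the sum of their radii, producing the
#' touching/overlapping clusters typical of smears; the remaining cells are
#' placed by rejection sampling so they do not touch.
#'
#' Instance labels partition the union of cell supports: a pixel covered by
#' several cells is assigned to the cell whose normalized elliptic radius
#' is smallest there. Boxes are recomputed from the final mask, so each box
#' is exactly the tight bound of its component.
#'
#' @param params a [SceneParams-class] object.
#' @param max_retries rejection-sampling cap per cell before giving up with
#'   an infeasible-packing error.
#' @return a [BloodCellScene-class] object.
#' @export
#' @examples
#' sc <- generateScene(sceneParams(image_height = 96, image_width = 96,
#'                                 n_cells = 5, seed = 7))
#' nrow(sceneBoxes(sc))
generateScene <- function(params, max_retries = 1000) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  m <- as.integer(params@image_height); n <- as.integer(params@image_width)
  withSeed(as.integer(params@seed), {
    ## background with a linear illumination ramp in a random direction
    bg <- matrix(params@background_intensity, m, n)
    if (params@gradient_strength > 0) {
      th <- runif(1, 0, 2 * pi)
      x <- matrix(seq_len(n) - 0.5, m, n, byrow = TRUE) / n - 0.5
      y <- matrix(seq_len(m) - 0.5, m, n) / m - 0.5
      bg <- bg + params@gradient_strength * (cos(th) * x + sin(th) * y)
      bg <- pmin(pmax(bg, 0), 1)
    }
    k <- as.integer(params@n_cells)
    cells <- placeCells(params, m, n, max_retries)
    canvas <- bg
    rhoMin <- array(Inf, c(m, n)); lab <- matrix(0L, m, n)
    if (k > 0) {
      for (i in seq_len(k)) {
        ci <- cells[i, ]
        canvas <- renderCell(canvas, c(ci$cx, ci$cy), c(ci$a, ci$b),
                             ci$theta, ci$intensity)
        rho <- ellipticRadius(m, n, c(ci$cx, ci$cy), c(ci$a, ci$b), ci$theta)
        take <- rho <= 1 & rho < rhoMin
        lab[take] <- i
        rhoMin[take] <- rho[take]
      }
      if (length(setdiff(seq_len(k), unique(as.vector(lab)))) > 0)
        stop("infeasible packing: a cell was fully occluded; ",
             "reduce n_cells or overlap_fraction")
    }
    img <- addNoise(canvas, params@noise_sigma, params@speckle_strength,
                    seed = NULL)
    boxes <- maskToBoxes(lab)
    new("BloodCellScene", image = img, boxes = boxes, mask = lab,
        params = params)
  })
}

## sample cell geometry: isolated cells by rejection, clustered cells
## attached to a previously placed cell at sub-contact distance
placeCells <- function(params, m, n, max_retries) {
  k <- as.integer(params@n_cells)
  cols <- c("cx", "cy", "a", "b", "theta", "intensity")
  cells <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                dimnames = list(NULL, cols)))
  if (k == 0) return(cells)
  ## a touching pair contributes two clustered cells, so the number of
  ## attached cells is half the targeted clustered fraction (hosts count)
  n_over <- floor(params@overlap_fraction * k / 2 + 0.5)
  if (n_over >= k && k > 1) n_over <- k - 1  # need at least one host
  if (k == 1) n_over <- 0
  n_iso <- k - n_over
  sampleGeom <- function() {
    a <- runif(1, params@radius_range[1], params@radius_range[2])
    e <- runif(1, params@eccentricity_range[1], params@eccentricity_range[2])
    b <- a * sqrt(1 - e^2)
    list(a = a, b = b, theta = runif(1, 0, pi),
         intensity = min(max(params@cell_intensity + runif(1, -0.05, 0.05),
                             0), 1))
  }
  ## isolated ("non-overlapping") cells keep a 3 px clearance between
  ## supports: the threshold+morphology chain expands the foreground by one
  ## pixel, so anything closer would merge into one component by
  ## construction rather than by segmentation error
  margin <- 3
  if (2 * (params@radius_range[2] + margin) >= min(m, n))
    stop("infeasible packing: cell radius too large for the image")
  for (i in seq_len(n_iso)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      g <- sampleGeom()
      cx <- runif(1, g$a + margin, n - g$a - margin)
      cy <- runif(1, g$a + margin, m - g$a - margin)
      if (nrow(cells) > 0) {
        d <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
        if (any(d < cells$a + g$a + margin)) next
      }
      cells[nrow(cells) + 1, ] <- c(cx, cy, g$a, g$b, g$theta, g$intensity)
      ok <- TRUE
      break
    }
    if (!ok) stop("infeasible packing: could not place ", k,
                  " cells of radius [", params@radius_range[1], ", ",
                  params@radius_range[2], "] in a ", m, "x", n,
                  " image within ", max_retries, " retries")
  }
  ## attach clustered cells to distinct hosts where possible so one
  ## attachment yields one touching pair
  hostPool <- sample.int(n_iso)
  for (i in seq_len(n_over)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      g <- sampleGeom()
      hostIdx <- if (i <= length(hostPool)) hostPool[i] else
        sample.int(nrow(cells), 1)
      host <- cells[hostIdx, ]
      d <- runif(1, 0.55, 0.9) * (host$a + g$a)
      th <- runif(1, 0, 2 * pi)
      cx <- host$cx + d * cos(th); cy <- host$cy + d * sin(th)
      if (cx < g$a / 2 || cx > n - g$a / 2 ||
          cy < g$a / 2 || cy > m - g$a / 2) next
      cells[nrow(cells) + 1, ] <- c(cx, cy, g$a, g$b, g$theta, g$intensity)
      ok <- TRUE
      break
    }
    if (!ok) stop("infeasible packing: could not attach clustered cell")
  }
  cells
}

## tight bounding boxes (0-based half-open) of the labels in an instance mask
maskToBoxes <- function(lab) {
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0L) return(detectionTable(matrix(numeric(0), 0, 4)))
  rows <- t(vapply(labs, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
  }, numeric(4)))
  detectionTable(rows, score = 1, label = "rbc")
}

#' Generate a batch of scenes with independent seeds
#'
#' Convenience wrapper producing `n` scenes whose seeds are derived from
#' `seed` (seed, seed+1, ...), with all other parameters shared.
#'
#' @param n number of scenes.
#' @param params template [SceneParams-class].
#' @param seed integer base seed.
#' @return list of [BloodCellScene-class] objects.
#' @export
simulateScenes <- function(n, params = sceneParams(), seed = 1) {
  lapply(seq_len(n), function(i) {
    p <- params
    p@seed <- seed + i - 1
    generateScene(p)
  })
}
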