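#' Parameters of a synthetic blood-smear scene
#'
#' Describes one simulated field of view: canvas size, cell count and
#' geometry, intensity levels and the noise model. Cells are rendered darker
#' than the background by default so that low intensity marks foreground,
#' the convention the segmentation stage assumes; set
#' `cell_intensity > background_intensity` for bright-cell imagery and use
#' the segmentation `polarity` switch.
#'
#' @slot image_height,image_width canvas size in pixels.
#' @slot n_cells number of cells to render.
#' @slot radius_range min/max semi-major axis in pixels.
#' @slot eccentricity_range min/max ellipse eccentricity in \[0, 1).
#' @slot overlap_fraction target fraction of cells placed in touching
#'   clusters (center distance below the sum of radii), in \[0, 1\].
#' @slot cell_intensity,background_intensity normalized intensities in
#'   \[0, 1\].
#' @slot gradient_strength peak-to-peak amplitude of a linear background
#'   illumination ramp (0 disables it).
#' @slot noise_sigma standard deviation of additive Gaussian noise.
#' @slot speckle_strength relative amplitude of multiplicative speckle
#'   noise.
#' @slot seed integer RNG seed.
#' @seealso [sceneParams()], [generateScene()]
#' @export
setClass("SceneParams",
  representation(image_height = "numeric", image_width = "numeric",
                 n_cells = "numeric", radius_range = "numeric",
                 eccentricity_range = "numeric", overlap_fraction = "numeric",
                 cell_intensity = "numeric", background_intensity = "numeric",
                 gradient_strength = "numeric", noise_sigma = "numeric",
                 speckle_strength = "numeric", seed = "numeric"),
  prototype(image_height = 256, image_width = 256, n_cells = 30,
            radius_range = c(8, 14), eccentricity_range = c(0, 0.4),
            overlap_fraction = 0.2, cell_intensity = 0.35,
            background_intensity = 0.85, gradient_strength = 0.05,
            noise_sigma = 0.02, speckle_strength = 0.05, seed = 1),
  validity = function(object) {
    msg <- character(0)
    if (object@image_height < 1 || object@image_width < 1)
      msg <- c(msg, "image dimensions must be positive")
    if (object@n_cells < 0) msg <- c(msg, "n_cells must be >= 0")
    if (length(object@radius_range) != 2 ||
        object@radius_range[1] > object@radius_range[2] ||
        object@radius_range[1] <= 0)
      msg <- c(msg, "radius_range must be positive with min <= max")
    if (length(object@eccentricity_range) != 2 ||
        any(object@eccentricity_range < 0) ||
        any(object@eccentricity_range >= 1) ||
        object@eccentricity_range[1] > object@eccentricity_range[2])
      msg <- c(msg, "eccentricity_range must lie in [0, 1) with min <= max")
    if (object@overlap_fraction < 0 || object@overlap_fraction > 1)
      msg <- c(msg, "overlap_fraction must be in [0, 1]")
    ints <- c(object@cell_intensity, object@background_intensity)
    if (any(ints < 0) || any(ints > 1))
      msg <- c(msg, "intensities must be in [0, 1]")
    if (object@noise_sigma < 0) msg <- c(msg, "noise_sigma must be >= 0")
    if (object@speckle_strength < 0)
      msg <- c(msg, "speckle_strength must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SceneParams constructor; any subset of the slots can be
#'   overridden by name.
#' @param ... named slot values overriding the defaults.
#' @return a validated `SceneParams` object.
#' @export
#' @examples
#' sceneParams(n_cells = 10, noise_sigma = 0)
sceneParams <- function(...) {
  obj <- new("SceneParams", ...)
  validObject(obj)
  obj
}

#' A synthetic scene with exact ground truth
#'
#' Bundles a rendered grayscale image with its ground-truth annotation: one
#' tight bounding box per cell and an integer instance mask in which pixel
#' value `k` marks cell `k` (0 is background). The validity method enforces
#' the ground-truth contract: the number of boxes equals the number of
#' distinct nonzero mask labels and each box is the tight bounding box of
#' its mask component.
#'
#' @slot image numeric matrix in \[0, 1\].
#' @slot boxes detection data.frame (see [detectionTable()]) with score 1.
#' @slot mask integer matrix of instance labels, same shape as `image`.
#' @slot params the generating `SceneParams`.
#' @seealso [generateScene()], [sceneImage()], [sceneBoxes()],
#'   [instanceMask()]
#' @export
setClass("BloodCellScene",
  representation(image = "matrix", boxes = "data.frame", mask = "matrix",
                 params = "SceneParams"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@image) == dim(object@mask)))
      msg <- c(msg, "image and mask must have the same shape")
    labs <- sort(unique(object@mask[object@mask > 0]))
    if (length(labs) != nrow(object@boxes))
      msg <- c(msg, "number of boxes must equal number of mask labels")
    if (length(labs) && !identical(labs, seq_along(labs)))
      msg <- c(msg, "mask labels must be 1..K")
    for (k in seq_along(labs)) {
      w <- which(object@mask == labs[k], arr.ind = TRUE)
      tight <- c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
      got <- as.numeric(object@boxes[k, c("x0", "y0", "x1", "y1")])
      if (!isTRUE(all.equal(tight, got))) {
        msg <- c(msg, sprintf("box %d is not the tight bound of its mask", k))
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn BloodCellScene image accessor.
#' @param scene a `BloodCellScene`.
#' @export
sceneImage <- function(scene) scene@image

#' @describeIn BloodCellScene ground-truth box accessor.
#' @export
sceneBoxes <- function(scene) scene@boxes

#' @describeIn BloodCellScene instance-mask accessor.
#' @export
instanceMask <- function(scene) scene@mask

setMethod("show", "BloodCellScene", function(object) {
  cat(sprintf("BloodCellScene: %d x %d image, %d cells\n",
              nrow(object@image), ncol(object@image), nrow(object@boxes)))
  cat(sprintf("  intensity range [%.3f, %.3f]; seed %d\n",
              min(object@image), max(object@image),
              as.integer(object@params@seed)))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(paste0("SceneParams: %dx%d px, %d cells, radii [%g, %g], ",
                     "overlap %.2f\n"),
              as.integer(object@image_height), as.integer(object@image_width),
              as.integer(object@n_cells), object@radius_range[1],
              object@radius_range[2], object@overlap_fraction))
  cat(sprintf("  cell %.2f on background %.2f; noise sigma %.3f, speckle %.3f\n",
              object@cell_intensity, object@background_intensity,
              object@noise_sigma, object@speckle_strength))
})

#' A trained region-proposal RBC detector
#'
#' Holds the weights of the small convolutional backbone, the region
#' proposal head (per-anchor objectness score and four box-regression
#' coefficients) and the RoI classification head, together with the anchor
#' layout and training log. Created by [trainDetector()]; applied with
#' [detectCells()]; serialized with [saveDetector()] / [loadDetector()].
#'
#' @slot params named list of weight arrays.
#' @slot config detector configuration (anchor scales/ratios, stride,
#'   thresholds, training schedule).
#' @slot lossLog data.frame of per-epoch mean losses.
#' @slot version checkpoint format version string.
#' @export
setClass("RBCDetector",
  representation(params = "list", config = "list", lossLog = "data.frame",
                 version = "character"),
  validity = function(object) {
    need <- c("stride", "scales", "ratios")
    if (!all(need %in% names(object@config)))
      "config must contain stride, scales and ratios" else TRUE
  })

setMethod("show", "RBCDetector", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("RBCDetector: %d parameters, stride %d, scales {%s}\n",
              np, as.integer(object@config$stride),
              paste(object@config$scales, collapse = ", ")))
  if (nrow(object@lossLog)) {
    cat(sprintf("  trained %d epochs; final mean loss %.4f\n",
                nrow(object@lossLog),
                object@lossLog$loss[nrow(object@lossLog)]))
  }
})

#' @describeIn RBCDetector per-epoch training-loss log accessor.
#' @param model an `RBCDetector`.
#' @export
lossLog <- function(model) model@lossLog
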