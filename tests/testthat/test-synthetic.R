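test_that("empty scene is background plus noise with no annotations", {
  p <- sceneParams(image_height = 48, image_width = 48, n_cells = 0,
                   noise_sigma = 0, speckle_strength = 0,
                   gradient_strength = 0, background_intensity = 0.8,
                   seed = 3)
  sc <- generateScene(p)
  expect_equal(nrow(sceneBoxes(sc)), 0L)
  expect_true(all(instanceMask(sc) == 0))
  expect_equal(sceneImage(sc), matrix(0.8, 48, 48))
})

test_that("scene generation is bit-identical under a fixed seed", {
  p <- sceneParams(image_height = 80, image_width = 80, n_cells = 6,
                   seed = 17)
  a <- generateScene(p)
  b <- generateScene(p)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(instanceMask(a), instanceMask(b))
  expect_identical(sceneBoxes(a), sceneBoxes(b))
})

test_that("noise-free non-overlapping scenes have n_cells components", {
  p <- sceneParams(image_height = 200, image_width = 200, n_cells = 20,
                   radius_range = c(6, 10), overlap_fraction = 0,
                   noise_sigma = 0, speckle_strength = 0,
                   gradient_strength = 0, seed = 5)
  sc <- generateScene(p)
  thr <- (p@cell_intensity + p@background_intensity) / 2
  expect_equal(floodFillCount(sceneImage(sc) <= thr), 20L)
})

test_that("ground-truth boxes are tight bounds of mask components", {
  for (s in c(1, 9, 23)) {
    sc <- generateScene(sceneParams(image_height = 96, image_width = 96,
                                    n_cells = 6, overlap_fraction = 0.3,
                                    seed = s))
    expect_true(validObject(sc))  # validity enforces tightness + label count
    expect_equal(nrow(sceneBoxes(sc)), 6L)
  }
})

test_that("achieved overlap fraction tracks the target", {
  p <- sceneParams(image_height = 220, image_width = 220, n_cells = 20,
                   radius_range = c(7, 10), overlap_fraction = 0.3,
                   seed = 12)
  sc <- generateScene(p)
  bx <- boxMatrix <- as.matrix(sceneBoxes(sc)[, c("x0", "y0", "x1", "y1")])
  cx <- (bx[, 1] + bx[, 3]) / 2; cy <- (bx[, 2] + bx[, 4]) / 2
  rad <- (bx[, 3] - bx[, 1] + bx[, 4] - bx[, 2]) / 4
  touching <- rep(FALSE, nrow(bx))
  for (i in seq_len(nrow(bx) - 1)) for (j in (i + 1):nrow(bx)) {
    d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
    if (d < rad[i] + rad[j]) touching[c(i, j)] <- TRUE
  }
  expect_lt(abs(mean(touching) - 0.3), 0.1 + 1e-9)
})

test_that("infeasible packings fail loudly", {
  p <- sceneParams(image_height = 40, image_width = 40, n_cells = 50,
                   radius_range = c(8, 10), overlap_fraction = 0, seed = 1)
  expect_error(generateScene(p), "infeasible")
})

test_that("renderCell respects intensity, symmetry and area", {
  canvas <- matrix(0.5, 41, 41)
  # same intensity as the canvas: nothing changes
  expect_equal(renderCell(canvas, c(20.5, 20.5), c(8, 8), 0.7, 0.5), canvas)
  # circles are rotation invariant
  a <- renderCell(canvas, c(20.5, 20.5), c(8, 8), 0, 0.2)
  b <- renderCell(canvas, c(20.5, 20.5), c(8, 8), 1.1, 0.2)
  expect_equal(a, b)
  # hard-edged ellipse interior pixel count ~ pi * a * b
  e <- renderCell(matrix(1, 61, 61), c(30.5, 30.5), c(10, 5), 0, 0,
                  edge_width = 0)
  expect_lt(abs(sum(e < 1) - pi * 10 * 5) / (pi * 10 * 5), 0.05)
  expect_error(renderCell(canvas, c(20, 20), c(-1, 5), 0, 0.2), "positive")
  expect_error(renderCell(canvas, c(60, 20), c(5, 5), 0, 0.2), "inside")
})

test_that("addNoise is clipped, seeded and exact in the zero-noise limit", {
  img <- matrix(0.5, 256, 256)
  expect_identical(addNoise(img, 0, 0), img)
  noisy <- addNoise(img, noise_sigma = 0.05, speckle_strength = 0, seed = 8)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_true(sd(noisy - img) > 0.045 && sd(noisy - img) < 0.055)
  expect_identical(noisy, addNoise(img, 0.05, 0, seed = 8))
  expect_error(addNoise(img, -0.1, 0), ">= 0")
})
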