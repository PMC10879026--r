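test_that("an all-zero config yields the exact identity", {
  cfg <- augmentConfig(rotation_range = 0, width_shift = 0, height_shift = 0,
                       shear_range = 0, zoom_range = 0,
                       horizontal_flip = FALSE)
  tr <- sampleTransform(cfg, c(32, 32), seed = 1)
  expect_identical(tr$matrix, diag(3))
  img <- matrix(runif(32 * 32), 32, 32)
  boxes <- detectionTable(rbind(c(3, 4, 10, 12), c(20, 20, 30, 30)))
  out <- applyTransform(img, boxes, tr)
  expect_identical(out$image, img)
  expect_equal(out$boxes, boxes)
})

test_that("transform sampling is seeded and stays inside its ranges", {
  cfg <- augmentConfig()
  t1 <- sampleTransform(cfg, c(64, 64), seed = 5)
  t2 <- sampleTransform(cfg, c(64, 64), seed = 5)
  expect_identical(t1, t2)
  angles <- vapply(1:2000, function(i)
    sampleTransform(cfg, c(64, 64), seed = i)$components$angle, numeric(1))
  expect_lte(max(abs(angles)), 0.2)
  expect_lt(abs(mean(angles)), 0.01)
  zooms <- vapply(1:500, function(i)
    sampleTransform(cfg, c(64, 64), seed = i)$components$zoom, numeric(1))
  expect_true(all(zooms >= 0.5 & zooms <= 1.5))
})

test_that("horizontal flip mirrors boxes and is an involution", {
  n <- 10
  flip <- affineTransform(matrix(c(-1, 0, 0, 0, 1, 0, n, 0, 1), 3))
  img <- matrix(runif(n * n), n, n)
  boxes <- detectionTable(matrix(c(2, 1, 5, 4), 1))
  once <- applyTransform(img, boxes, flip)
  expect_equal(as.numeric(once$boxes[1, c("x0", "x1")]), c(5, 8))
  twice <- applyTransform(once$image, once$boxes, flip)
  expect_identical(twice$image, img)
  expect_equal(twice$boxes, boxes)
})

test_that("rescale converts raw 8-bit intensities onto the unit scale", {
  raw8 <- matrix(255, 6, 6)
  tr <- affineTransform(diag(3), rescale = 1 / 255)
  expect_equal(applyTransform(raw8, t = tr)$image, matrix(1, 6, 6))
})

test_that("transformed boxes contain their warped mask pixels", {
  sc <- generateScene(sceneParams(image_height = 96, image_width = 96,
                                  n_cells = 4, overlap_fraction = 0,
                                  seed = 21))
  img <- sceneImage(sc); mask <- instanceMask(sc)
  cfg <- augmentConfig(zoom_range = 0.2)
  boxes <- sceneBoxes(sc)
  boxes$cellid <- seq_len(nrow(boxes))   # survives the transform's subset
  for (s in 1:5) {
    tr <- sampleTransform(cfg, dim(img), seed = s)
    out <- applyTransform(img, boxes, tr)
    if (nrow(out$boxes) == 0) next
    # warp the instance mask with the same map (nearest neighbor)
    Ainv <- solve(tr$matrix)
    xc <- rep(seq_len(96) - 0.5, each = 96)
    yc <- rep(seq_len(96) - 0.5, times = 96)
    src <- Ainv %*% rbind(xc, yc, 1)
    si <- round(src[2, ] + 0.5); sj <- round(src[1, ] + 0.5)
    ok <- si >= 1 & si <= 96 & sj >= 1 & sj <= 96
    dst <- cbind(rep(seq_len(96), times = 96), rep(seq_len(96), each = 96))
    warped <- matrix(0L, 96, 96)
    warped[dst[ok, , drop = FALSE]] <- mask[cbind(si, sj)[ok, , drop = FALSE]]
    for (r in seq_len(nrow(out$boxes))) {
      b <- as.numeric(out$boxes[r, c("x0", "y0", "x1", "y1")])
      px <- which(warped == out$boxes$cellid[r], arr.ind = TRUE)
      if (nrow(px) < 10) next
      inside <- px[, 2] - 0.5 >= b[1] - 0.5 & px[, 2] - 0.5 <= b[3] + 0.5 &
                px[, 1] - 0.5 >= b[2] - 0.5 & px[, 1] - 0.5 <= b[4] + 0.5
      expect_gte(mean(inside), 0.9)
    }
  }
})

test_that("augmentScene draws k reproducible variants", {
  sc <- generateScene(sceneParams(image_height = 96, image_width = 96,
                                  n_cells = 3, seed = 2))
  a <- augmentScene(sc, augmentConfig(), k = 3, seed = 7)
  b <- augmentScene(sc, augmentConfig(), k = 3, seed = 7)
  expect_length(a, 3)
  expect_identical(a, b)
})
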