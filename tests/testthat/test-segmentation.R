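test_that("threshold selection matches an exhaustive Otsu search", {
  img <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
  T <- selectThreshold(img)
  expect_gt(T, 0.2); expect_lt(T, 0.8)
  # any cut between the two values maximizes between-class variance; the
  # exhaustive search must also land strictly between them
  expect_gt(bruteOtsu(img), 0.2); expect_lt(bruteOtsu(img), 0.8)
  expect_equal(selectThreshold(img, method = "fixed", value = 0.5), 0.5)
  expect_error(selectThreshold(matrix(0.3, 5, 5)), "constant")
  # bimodal synthetic scene: class means fall on opposite sides of T
  sc <- generateScene(sceneParams(image_height = 120, image_width = 120,
                                  n_cells = 8, noise_sigma = 0.02, seed = 4))
  img2 <- sceneImage(sc)
  T2 <- selectThreshold(img2)
  expect_lt(mean(img2[instanceMask(sc) > 0]), T2)
  expect_gt(mean(img2[instanceMask(sc) == 0]), T2)
  expect_equal(T2, bruteOtsu(img2), tolerance = 1 / 256)
})

test_that("threshold split partitions the grid with the boundary in F", {
  img <- matrix(c(0.1, 0.9, 0.5, 0.5), 2, 2, byrow = TRUE)
  bf <- thresholdSplit(img, 0.5)
  expect_equal(bf$F, matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_true(all(bf$B + bf$F == 1))
  expect_equal(thresholdSplit(matrix(0.9, 3, 3), 0.5)$B, matrix(1, 3, 3))
  expect_equal(img[img == 0.5] <= 0.5, c(TRUE, TRUE))  # boundary is foreground
})

test_that("erosion and dilation follow the min/max definitions", {
  S <- structuringElement("square", 3)
  ones <- matrix(1, 6, 6)
  er <- erodeMask(ones, S)
  expect_true(all(er[2:5, 2:5] == 1))
  expect_true(all(er[1, ] == 0) && all(er[, 6] == 0))  # border: OOB = 0
  single <- matrix(0, 7, 7); single[4, 4] <- 1
  expect_equal(erodeMask(single, S), matrix(0, 7, 7))
  expect_equal(sum(dilateMask(single, S)), 9)
  expect_true(all(dilateMask(single, S)[3:5, 3:5] == 1))
  empty <- matrix(0, 5, 5)
  expect_equal(erodeMask(empty, S), empty)
  expect_equal(dilateMask(empty, S), empty)
  expect_equal(dilateMask(ones, S), ones)
})

test_that("morphology obeys ordering, duality and random-mask oracles", {
  set.seed(11)
  S <- structuringElement("square", 3)
  for (k in 1:5) {
    M <- matrix(rbinom(100, 1, 0.4), 10, 10)
    er <- erodeMask(M, S); di <- dilateMask(M, S)
    expect_true(all(er <= M))            # anti-extensive
    expect_true(all(M <= di))            # extensive
    # duality on interior pixels for the symmetric element
    dual <- 1 - dilateMask(1 - M, S)
    expect_equal(er[2:9, 2:9], dual[2:9, 2:9])
    # brute-force min/max over offsets
    for (i in 2:9) for (j in 2:9) {
      nb <- M[(i - 1):(i + 1), (j - 1):(j + 1)]
      expect_equal(er[i, j], min(nb))
      expect_equal(di[i, j], max(nb))
    }
  }
})

test_that("the combination rule matches its truth table exactly", {
  f <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(combineMasks(f, b), matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(combineMasks(matrix(1, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("component counting honors connectivity and min_area", {
  empty <- matrix(0, 10, 10)
  expect_equal(countCells(empty, 1)$count, 0L)
  M <- matrix(0, 20, 20)
  M[2:6, 2:6] <- 1; M[10:14, 12:16] <- 1
  res <- countCells(M, min_area = 1)
  expect_equal(res$count, 2L)
  expect_equal(res$count, floodFillCount(M))
  expect_equal(as.numeric(res$regions[1, c("x0", "y0", "x1", "y1")]),
               c(1, 1, 6, 6))
  expect_equal(res$regions$area, c(25L, 25L))
  # diagonal touch merges under 8-connectivity
  D <- matrix(0, 5, 5); D[1, 1] <- 1; D[2, 2] <- 1
  expect_equal(countCells(D, 1)$count, 1L)
  # min_area discards the smaller block
  expect_equal(countCells(M, min_area = 26)$count, 0L)
})

test_that("the full chain recovers the true count on clean scenes", {
  p <- sceneParams(image_height = 200, image_width = 200, n_cells = 20,
                   radius_range = c(6, 10), overlap_fraction = 0,
                   noise_sigma = 0, speckle_strength = 0,
                   gradient_strength = 0, seed = 31)
  sc <- generateScene(p)
  res <- segmentCells(sceneImage(sc))
  expect_equal(res$count, 20L)
  # the result mask is always inside the dilated foreground
  bf <- thresholdSplit(sceneImage(sc), res$threshold)
  expect_true(all(res$mask <= dilateMask(bf$F)))
  # bright-cell polarity works through the same chain
  inv <- generateScene(p)
  res2 <- segmentCells(1 - sceneImage(inv), polarity = "bright")
  expect_equal(res2$count, 20L)
})
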