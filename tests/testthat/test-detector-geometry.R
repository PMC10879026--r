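test_that("anchor grids tile the stride lattice with area-preserving ratios", {
  a <- generateAnchors(c(64, 64), stride = 8, scales = c(12, 20), ratios = 1)
  expect_equal(nrow(a), 8 * 8 * 2)
  g <- attr(a, "grid")
  expect_equal(unname(g[1:2]), c(8, 8))
  # scale s at ratio 1 gives an s x s box
  w <- a[, 3] - a[, 1]; h <- a[, 4] - a[, 2]
  expect_true(all(sort(unique(w)) == c(12, 20)))
  expect_equal(w, h)
  # centers on the lattice midpoints
  cx <- (a[, 1] + a[, 3]) / 2
  expect_true(all((cx - 4) %% 8 == 0))
  # non-unit ratios keep the area
  b <- generateAnchors(c(32, 32), 8, scales = 16, ratios = c(1, 2))
  area <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  expect_equal(unique(round(area, 9)), 256)
  expect_error(generateAnchors(c(32, 32), 8, numeric(0), 1), "non-empty")
})

test_that("box decoding matches the center/log-size parameterization", {
  a <- matrix(c(10, 10, 20, 22), 1)        # w = 10, h = 12
  expect_equal(decodeBoxes(a, matrix(0, 1, 4)), a,
               ignore_attr = TRUE)
  shifted <- decodeBoxes(a, matrix(c(1, 0, 0, 0), 1))
  expect_equal((shifted[1] + shifted[3]) / 2, 25)   # center moved +w
  doubled <- decodeBoxes(a, matrix(c(0, 0, log(2), 0), 1))
  expect_equal(doubled[3] - doubled[1], 20)
  # encode is the exact inverse
  set.seed(6)
  anchors <- cbind(runif(20, 0, 50), runif(20, 0, 50), 0, 0)
  anchors[, 3] <- anchors[, 1] + runif(20, 5, 30)
  anchors[, 4] <- anchors[, 2] + runif(20, 5, 30)
  t <- matrix(rnorm(80, sd = 0.3), 20, 4)
  expect_equal(encodeBoxes(anchors, decodeBoxes(anchors, t)), t,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(decodeBoxes(a, matrix(NA_real_, 1, 4)), "finite")
})

test_that("proposal filtering clips, prunes small boxes and sorts stably", {
  cfg <- proposalConfig(pre_nms_topN = 6000, post_nms_topN = 300,
                        min_size = 16)
  out <- filterProposals(matrix(c(-5, -5, 10, 10), 1), 0.9, c(64, 64),
                         proposalConfig(min_size = 1))
  expect_equal(out$boxes, matrix(c(0, 0, 10, 10), 1), ignore_attr = TRUE)
  # a 10-px-wide box dies at min_size 16
  out2 <- filterProposals(rbind(c(0, 0, 10, 40), c(0, 0, 40, 40)),
                          c(0.9, 0.1), c(64, 64), cfg)
  expect_equal(nrow(out2$boxes), 1L)
  expect_equal(out2$index, 2L)
  # large random batch: exactly pre_nms_topN survive, scores non-increasing
  set.seed(13)
  n <- 10000
  bx <- cbind(runif(n, 0, 40), runif(n, 0, 40), 0, 0)
  bx[, 3] <- bx[, 1] + runif(n, 16, 30); bx[, 4] <- bx[, 2] + runif(n, 16, 30)
  sc <- runif(n)
  out3 <- filterProposals(bx, sc, c(100, 100), cfg)
  expect_equal(nrow(out3$boxes), 6000L)
  expect_true(all(diff(out3$scores) <= 0))
  expect_equal(out3$scores, sort(sc, decreasing = TRUE)[1:6000])
  # ties broken by original index
  out4 <- filterProposals(rbind(c(0, 0, 20, 20), c(5, 5, 25, 25)),
                          c(0.5, 0.5), c(64, 64),
                          proposalConfig(min_size = 1))
  expect_equal(out4$index, c(1L, 2L))
  expect_equal(filterProposals(matrix(numeric(0), 0, 4), numeric(0),
                               c(64, 64), cfg)$index, integer(0))
})

test_that("greedy NMS equals the brute-force reference", {
  one <- nmsBoxes(matrix(c(0, 0, 10, 10), 1), 0.7)
  expect_equal(one$index, 1L)
  two <- nmsBoxes(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)), c(0.4, 0.9), 0.5)
  expect_equal(two$index, 2L)
  tie <- nmsBoxes(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)), c(0.7, 0.7), 0.5)
  expect_equal(tie$index, 1L)             # tie -> lower index
  set.seed(99)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    bx <- cbind(runif(n, 0, 60), runif(n, 0, 60), 0, 0)
    bx[, 3] <- bx[, 1] + runif(n, 4, 25); bx[, 4] <- bx[, 2] + runif(n, 4, 25)
    sc <- runif(n)
    thr <- runif(1, 0.2, 0.7)
    expect_equal(nmsBoxes(bx, sc, thr)$index, bruteNMS(bx, sc, thr))
  }
})

test_that("RoI pooling reproduces the per-bin max reference", {
  fm <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(roiPool(fm, c(0, 0, 4, 4), c(2, 2))[1, , , 1],
               matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  # whole constant map pools to a constant
  expect_true(all(roiPool(matrix(3.5, 6, 6), c(0, 0, 6, 6), c(3, 3)) == 3.5))
  # aligned integer RoI with matching output size is the identity
  expect_equal(roiPool(fm, c(1, 1, 3, 3), c(2, 2))[1, , , 1], fm[2:3, 2:3])
  set.seed(21)
  for (k in 1:20) {
    fm <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    roi <- c(runif(2, 0, 4), 0, 0); roi[3:4] <- roi[1:2] + runif(2, 1, 4)
    os <- c(sample(1:3, 1), sample(1:3, 1))
    got <- roiPool(fm, roi, os)
    expect_equal(c(got[1, , , ]), c(naiveRoiPool(fm, roi, os)))
  }
})

test_that("the multi-task loss combines CE and smooth-L1 as stated", {
  # perfect predictions: both terms vanish
  perfect <- multitaskLoss(matrix(c(100, -100), 1), 1L,
                           matrix(0, 1, 4), matrix(0, 1, 4), TRUE)
  expect_equal(as.numeric(perfect), 0)
  # probability 1/2 on the true class, exact boxes: ln 2
  half <- multitaskLoss(matrix(c(0, 0), 1), 1L, matrix(0, 1, 4),
                        matrix(0, 1, 4), TRUE)
  expect_equal(as.numeric(half), log(2))
  # |error| 0.5 per coordinate sits on the quadratic branch: 0.125 each
  l <- multitaskLoss(matrix(c(100, -100), 1), 1L,
                     matrix(0.5, 1, 4), matrix(0, 1, 4), TRUE)
  expect_equal(as.numeric(l), 4 * 0.125)
  expect_equal(attr(l, "loc"), 0.5)
  expect_equal(smoothL1(0.5), 0.125)
  expect_equal(smoothL1(2), 1.5)          # linear branch
  # no positives: localization contributes nothing
  noloc <- multitaskLoss(matrix(c(0, 0), 1), 2L, matrix(9, 1, 4),
                         matrix(0, 1, 4), FALSE)
  expect_equal(as.numeric(noloc), log(2))
  expect_error(multitaskLoss(matrix(numeric(0), 0, 2), integer(0),
                             matrix(numeric(0), 0, 4),
                             matrix(numeric(0), 0, 4), logical(0)),
               "sample")
})

test_that("detection labeling rasterizes the union of surviving boxes", {
  empty <- labelCells(c(8, 8), detectionTable(matrix(numeric(0), 0, 4)))
  expect_true(all(empty == 0))
  one <- labelCells(c(8, 8), detectionTable(matrix(c(2, 2, 5, 5), 1), 0.9),
                    area_range = NULL)
  expect_equal(sum(one), 9)
  expect_equal(which(one == 1, arr.ind = TRUE)[, "row"], rep(3:5, 3),
               ignore_attr = TRUE)
  # overlapping boxes: a set union, still strictly binary
  two <- labelCells(c(10, 10),
                    detectionTable(rbind(c(1, 1, 5, 5), c(3, 3, 7, 7)), 0.9),
                    area_range = NULL)
  expect_true(all(two %in% c(0, 1)))
  expect_equal(sum(two), 16 + 16 - 4)
  # the score gate removes weak detections
  gated <- labelCells(c(8, 8), detectionTable(matrix(c(2, 2, 5, 5), 1), 0.2),
                      score_threshold = 0.5)
  expect_true(all(gated == 0))
})
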