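test_that("greedy matching conserves counts and applies the IoU gate", {
  truths <- detectionTable(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30),
                                 c(40, 0, 50, 10)))
  exact <- matchDetections(truths, truths)
  expect_equal(c(exact$tp, exact$fp, exact$fn), c(3, 0, 0))
  none <- matchDetections(truths[0, ], detectionTable(matrix(runif(20), 5)))
  expect_equal(c(none$tp, none$fn), c(0, 5))
  # boxes shifted to IoU ~0.43 < 0.5: everything unmatched
  shifted <- truths
  shifted[, c("x0", "x1")] <- shifted[, c("x0", "x1")] + 4
  m <- matchDetections(shifted, truths, 0.5)
  expect_equal(boxIoU(shifted, truths)[1, 1], 6 / 14, tolerance = 1e-12)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 3, 3))
  # ...but matched at a looser threshold
  m2 <- matchDetections(shifted, truths, 0.4)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(3, 0, 0))
  # count conservation on random instances, each truth matched once
  set.seed(40)
  for (k in 1:10) {
    np <- sample(1:8, 1); nt <- sample(1:8, 1)
    pm <- cbind(runif(np, 0, 30), runif(np, 0, 30), 0, 0)
    pm[, 3] <- pm[, 1] + runif(np, 3, 12)
    pm[, 4] <- pm[, 2] + runif(np, 3, 12)
    tm <- cbind(runif(nt, 0, 30), runif(nt, 0, 30), 0, 0)
    tm[, 3] <- tm[, 1] + runif(nt, 3, 12)
    tm[, 4] <- tm[, 2] + runif(nt, 3, 12)
    mm <- matchDetections(detectionTable(pm, runif(np)),
                          detectionTable(tm), 0.3)
    expect_equal(mm$tp + mm$fp, np)
    expect_equal(mm$tp + mm$fn, nt)
    expect_false(any(duplicated(mm$matches$truth)))
    expect_true(all(mm$matches$iou >= 0.3))
  }
})

test_that("metrics follow their defining ratios with safe degenerate cases", {
  m <- computeMetrics(list(tp = 8, fp = 2, fn = 2))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$accuracy, 8 / 12)
  expect_equal(m$f1, 0.8)
  expect_false(m$degenerate)
  z <- computeMetrics(list(tp = 0, fp = 0, fn = 0))
  expect_true(z$degenerate)
  expect_equal(unlist(z[1:4]), c(precision = 0, recall = 0, f1 = 0,
                                 accuracy = 0))
  perfect <- computeMetrics(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect[1:4]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
})

test_that("holdout splits are 60/20/20, disjoint and seeded", {
  s <- makeSplits(100, "holdout", seed = 4)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 60, validation = 20, test = 20))
  expect_equal(sort(c(s$train, s$validation, s$test)), 1:100)
  expect_identical(makeSplits(100, "holdout", seed = 4), s)
  expect_false(identical(makeSplits(100, "holdout", seed = 5), s))
})

test_that("k-fold rotations are disjoint, exhaustive and balanced", {
  s <- makeSplits(10, "kfold", k = 10, seed = 2)
  expect_true(all(lengths(s$folds) == 1))
  expect_equal(sort(unlist(s$folds)), 1:10)
  s2 <- makeSplits(23, "kfold", k = 5, seed = 3)
  expect_lte(diff(range(lengths(s2$folds))), 1)
  expect_equal(sort(unlist(s2$folds)), 1:23)
  for (r in s2$rotations) {
    expect_equal(sort(c(r$train, r$test)), 1:23)
    expect_length(intersect(r$train, r$test), 0)
  }
  expect_error(makeSplits(4, "kfold", k = 10), ">= k")
})
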