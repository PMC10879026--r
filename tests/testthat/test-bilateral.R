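test_that("bilateral weights follow the Gaussian distance/range factors", {
  img <- matrix(0.5, 5, 5)
  w0 <- bilateralWeights(img, 3, 3, 3, 3, filterParams())
  expect_equal(unlist(w0), c(wd = 1, wr = 1, w = 1))
  w1 <- bilateralWeights(img, 3, 3, 3, 4, filterParams(sigma_d = 1))
  expect_equal(w1$wd, exp(-0.5))
  expect_equal(w1$w, exp(-0.5))          # equal intensities: wr = 1
  img[3, 4] <- 0.9
  w2 <- bilateralWeights(img, 3, 3, 3, 4, filterParams(sigma_r = 1e-4))
  expect_lt(w2$wr, 1e-12)                # sigma_r -> 0 kills unequal pairs
  expect_error(bilateralWeights(img, 0, 3, 3, 3), "bounds")
})

test_that("bilateral filter has its fixed points and stays in range", {
  const <- matrix(0.4, 9, 9)
  expect_equal(bilateralFilter(const, filterParams()), const)
  img <- matrix(runif(100), 10, 10)
  expect_identical(bilateralFilter(img, filterParams(window_radius = 0)), img)
  out <- bilateralFilter(img, filterParams(sigma_d = 2, sigma_r = 0.1))
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))
  img[2, 2] <- Inf
  expect_error(bilateralFilter(img, filterParams()), "finite")
})

test_that("optimized filter equals the quadruple-loop evaluation", {
  set.seed(42)
  for (k in 1:5) {
    m <- sample(5:16, 1); n <- sample(5:16, 1)
    img <- matrix(runif(m * n), m, n)
    fp <- filterParams(sigma_d = runif(1, 0.8, 2.5),
                       sigma_r = runif(1, 0.05, 0.4),
                       window_radius = sample(1:3, 1))
    expect_lt(max(abs(bilateralFilter(img, fp) - naiveBilateral(img, fp))),
              1e-10)
  }
})

test_that("weight normalization sums to one at every pixel", {
  set.seed(7)
  img <- matrix(runif(64), 8, 8)
  fp <- filterParams(sigma_d = 1.2, sigma_r = 0.15, window_radius = 2)
  out <- bilateralFilter(img, fp)
  for (i in 1:8) for (j in 1:8) {
    w <- c(); v <- c()
    for (p in max(1, i - 2):min(8, i + 2))
      for (q in max(1, j - 2):min(8, j + 2)) {
        w <- c(w, bilateralWeights(img, i, j, p, q, fp)$w)
        v <- c(v, img[p, q])
      }
    expect_lt(abs(sum(w / sum(w)) - 1), 1e-12)
    expect_gte(sum(w), 1)                     # center weight alone is 1
    # the filter output is exactly this normalized convex combination
    expect_equal(out[i, j], sum(w * v) / sum(w), tolerance = 1e-12)
  }
})

test_that("the sigma_r -> Inf limit is a plain Gaussian blur", {
  set.seed(3)
  img <- matrix(runif(144), 12, 12)
  fp <- filterParams(sigma_d = 1.5, sigma_r = 1e6, window_radius = 4)
  expect_lt(max(abs(bilateralFilter(img, fp) -
                    naiveGaussianBlur(img, 1.5, 4))), 1e-6)
})

test_that("iteration converges on constants and smooths monotonically", {
  const <- matrix(0.7, 8, 8)
  out <- iterateFilter(const, filterParams(n_iterations = 5))
  expect_equal(as.numeric(attr(out, "iterations")), 1)
  attr(out, "iterations") <- NULL
  expect_equal(out, const)
  set.seed(9)
  img <- matrix(0.5, 20, 20)
  img[cbind(sample(20, 12, TRUE), sample(20, 12, TRUE))] <- 1  # salt noise
  fp1 <- filterParams(sigma_d = 1.5, sigma_r = 0.5, n_iterations = 1,
                      convergence_tol = 0)
  fp5 <- filterParams(sigma_d = 1.5, sigma_r = 0.5, n_iterations = 5,
                      convergence_tol = 0)
  tv <- function(x) sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
  expect_identical(c(iterateFilter(img, fp1)), c(bilateralFilter(img, fp1)))
  expect_lte(tv(iterateFilter(img, fp5)), tv(iterateFilter(img, fp1)))
})

test_that("radial gradient index scores blobs and flat fields correctly", {
  expect_equal(radialGradientIndex(matrix(0.5, 21, 21), c(10, 10), 5), 0)
  blob <- makeBlob(size = 81, center = c(24.5, 40.5), s = 6)
  expect_gte(radialGradientIndex(blob, c(24.5, 40.5), 12), 0.95)
  # three blob radii away the disc sees one-sided gradients only
  expect_lte(abs(radialGradientIndex(blob, c(24.5 + 18, 40.5), 6)), 0.3)
  # bright-center blob flips the sign
  expect_lte(radialGradientIndex(1 - blob, c(24.5, 40.5), 12), -0.95)
  expect_error(radialGradientIndex(blob, c(500, 500), 5), "intersect")
})
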