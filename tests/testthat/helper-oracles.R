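# Independent reference implementations used as oracles. These are written
# as directly as possible (quadruple loops, queues, O(n^2) scans) so they
# stay structurally independent of the optimized package code they check.

# direct quadruple-loop evaluation of the bilateral filter over the same
# truncated window as the package implementation
naiveBilateral <- function(image, params) {
  m <- nrow(image); n <- ncol(image)
  r <- params$window_radius
  out <- image
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0; W <- 0
    for (p in max(1, i - r):min(m, i + r)) {
      for (q in max(1, j - r):min(n, j + r)) {
        wd <- exp(-((i - p)^2 + (j - q)^2) / (2 * params$sigma_d^2))
        wr <- exp(-(image[i, j] - image[p, q])^2 / (2 * params$sigma_r^2))
        acc <- acc + wd * wr * image[p, q]
        W <- W + wd * wr
      }
    }
    out[i, j] <- acc / W
  }
  out
}

# plain Gaussian blur over the same window (distance weights only)
naiveGaussianBlur <- function(image, sigma_d, r) {
  m <- nrow(image); n <- ncol(image)
  out <- image
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0; W <- 0
    for (p in max(1, i - r):min(m, i + r)) {
      for (q in max(1, j - r):min(n, j + r)) {
        wd <- exp(-((i - p)^2 + (j - q)^2) / (2 * sigma_d^2))
        acc <- acc + wd * image[p, q]
        W <- W + wd
      }
    }
    out[i, j] <- acc / W
  }
  out
}

# queue-based flood fill, 8-connectivity; returns the component count
floodFillCount <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  seen <- matrix(FALSE, m, n)
  count <- 0L
  for (i0 in seq_len(m)) for (j0 in seq_len(n)) {
    if (mask[i0, j0] == 0 || seen[i0, j0]) next
    count <- count + 1L
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii >= 1 && ii <= m && jj >= 1 && jj <= n &&
            mask[ii, jj] != 0 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# O(n^2) greedy NMS reference: visit boxes by descending score (ties by
# index), keep a box unless it overlaps an already kept box above the
# threshold
bruteNMS <- function(boxes, scores, thr) {
  ord <- order(-scores)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (pairIoU(boxes[i, ], boxes[k, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

pairIoU <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- max(0, a[3] - a[1]) * max(0, a[4] - a[2]) +
        max(0, b[3] - b[1]) * max(0, b[4] - b[2]) - inter
  if (ua > 0) inter / ua else 0
}

# per-bin max-pooling reference with the same outward quantization
naiveRoiPool <- function(fm, roi, out_size, scale = 1) {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1))
  H <- dim(fm)[1]; W <- dim(fm)[2]; C <- dim(fm)[3]
  x0 <- max(0, floor(roi[1] * scale)); y0 <- max(0, floor(roi[2] * scale))
  x1 <- min(W, ceiling(roi[3] * scale)); y1 <- min(H, ceiling(roi[4] * scale))
  out <- array(0, c(out_size, C))
  for (by in seq_len(out_size[1])) for (bx in seq_len(out_size[2])) {
    ry <- c(floor(y0 + (y1 - y0) * (by - 1) / out_size[1]),
            ceiling(y0 + (y1 - y0) * by / out_size[1]))
    rx <- c(floor(x0 + (x1 - x0) * (bx - 1) / out_size[2]),
            ceiling(x0 + (x1 - x0) * bx / out_size[2]))
    if (ry[2] > ry[1] && rx[2] > rx[1]) {
      for (c_ in seq_len(C)) {
        out[by, bx, c_] <- max(fm[(ry[1] + 1):ry[2], (rx[1] + 1):rx[2], c_])
      }
    }
  }
  out
}

# exhaustive Otsu: maximize between-class variance over all bin cuts
bruteOtsu <- function(image, levels = 256) {
  bins <- pmin(floor(image * levels), levels - 1)
  h <- tabulate(bins + 1, levels)
  p <- h / sum(h)
  best <- -Inf; bestT <- 0
  for (t in 0:(levels - 2)) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- sum(((t + 1):(levels - 1)) * p[(t + 2):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestT <- t }
  }
  (bestT + 1) / levels
}

# a radially symmetric Gaussian blob (dark center on bright background)
makeBlob <- function(size = 41, center = NULL, s = 6, depth = 0.5,
                     bg = 0.9) {
  if (is.null(center)) center <- c(size / 2, size / 2)
  x <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  y <- t(x)
  bg - depth * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * s^2))
}

# scene parameters shared by the detector tests: small fields with a few
# cells, mild clustering and mild noise
detectorSceneParams <- function() {
  sceneParams(image_height = 64, image_width = 64, n_cells = 4,
              radius_range = c(5, 9), overlap_fraction = 0.25,
              noise_sigma = 0.02, speckle_strength = 0.03, seed = 1)
}

# one shared small detector, trained once per test run (cached)
.testModelEnv <- new.env(parent = emptyenv())
testDetector <- function() {
  if (is.null(.testModelEnv$model)) {
    scenes <- simulateScenes(60, detectorSceneParams(), seed = 400)
    .testModelEnv$model <- trainDetector(scenes, seed = 11)
  }
  .testModelEnv$model
}
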