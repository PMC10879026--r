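## Detection evaluation: greedy IoU matching of predictions to ground
## truth, the derived precision/recall/F1/accuracy metrics, and the data
## split protocols (60/20/20 holdout and k-fold cross-validation).

#' Match predicted boxes to ground-truth boxes
#'
#' Predictions are visited in descending score order; each is matched to
#' the unmatched truth box of highest IoU, provided that IoU reaches the
#' threshold. Every truth is matched at most once, so
#' `TP + FN = #truths` and `TP + FP = #predictions` always hold.
#'
#' @param predictions detection data.frame (or box matrix; scores default
#'   to 1 in input order).
#' @param truths detection data.frame or box matrix of ground-truth boxes.
#' @param iou_threshold minimum IoU of a valid match (default 0.5).
#' @return list of class `MatchResult` with counts `tp`, `fp`, `fn` and a
#'   data.frame `matches` (`pred`, `truth`, `iou`).
#' @export
matchDetections <- function(predictions, truths, iou_threshold = 0.5) {
  pm <- boxMatrix(predictions)
  tm <- boxMatrix(truths)
  scores <- if (is.data.frame(predictions) && !is.null(predictions$score))
    predictions$score else rep(1, nrow(pm))
  ord <- order(-scores)
  matchedT <- rep(FALSE, nrow(tm))
  rows <- list()
  if (nrow(tm) > 0L) {
    for (i in ord) {
      iou <- boxIoU(pm[i, , drop = FALSE], tm)[1, ]
      iou[matchedT] <- -1
      j <- which.max(iou)
      if (length(j) && iou[j] >= iou_threshold) {
        matchedT[j] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(pred = i, truth = j,
                                               iou = iou[j])
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  tp <- nrow(matches)
  structure(list(tp = tp, fp = nrow(pm) - tp, fn = nrow(tm) - tp,
                 matches = matches), class = "MatchResult")
}

#' Detection metrics from a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, and detection `accuracy = TP/(TP+FP+FN)` — the
#' fraction of all involved boxes that were correctly matched. Any ratio
#' with a zero denominator is reported as 0 and flagged `degenerate`.
#'
#' @param match a `MatchResult` from [matchDetections()], or a list with
#'   `tp`, `fp`, `fn`.
#' @return list with `precision`, `recall`, `f1`, `accuracy`,
#'   `degenerate`.
#' @export
computeMetrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (any(c(tp, fp, fn) < 0)) stop("negative counts")
  degenerate <- FALSE
  rat <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- rat(2 * precision * recall, precision + recall)
  accuracy <- rat(tp, tp + fp + fn)
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = accuracy, degenerate = degenerate)
}

#' Build train/validation/test splits
#'
#' `scheme = "holdout"` shuffles the items and splits 60/20/20
#' (validation and test sizes round to nearest, the remainder goes to
#' training). `scheme = "kfold"` assigns items to `k` folds whose sizes
#' differ by at most one and returns the k rotations as (train, test)
#' pairs. Deterministic for a fixed seed.
#'
#' @param n_items number of items to split.
#' @param scheme `"holdout"` or `"kfold"`.
#' @param k number of folds (k-fold only); requires `n_items >= k`.
#' @param seed integer seed for the shuffle.
#' @return for holdout, a list with `train`, `validation`, `test` index
#'   vectors; for k-fold, a list with `folds` (test indices per fold) and
#'   `rotations` (list of `train`/`test` pairs). Both carry `seed`.
#' @export
makeSplits <- function(n_items, scheme = c("holdout", "kfold"), k = 10,
                       seed = 1) {
  scheme <- match.arg(scheme)
  withSeed(seed, {
    perm <- sample.int(n_items)
    if (scheme == "holdout") {
      n_val <- round(0.2 * n_items)
      n_test <- round(0.2 * n_items)
      n_train <- n_items - n_val - n_test
      list(train = sort(perm[seq_len(n_train)]),
           validation = sort(perm[n_train + seq_len(n_val)]),
           test = sort(perm[n_train + n_val + seq_len(n_test)]),
           seed = seed)
    } else {
      if (n_items < k) stop("n_items must be >= k for k-fold splitting")
      fold <- rep(seq_len(k), length.out = n_items)
      folds <- lapply(seq_len(k), function(f) sort(perm[fold == f]))
      rotations <- lapply(seq_len(k), function(f) {
        list(train = sort(unlist(folds[-f])), test = folds[[f]])
      })
      list(folds = folds, rotations = rotations, seed = seed)
    }
  })
}

#' Evaluate a detector over a set of scenes
#'
#' Runs [detectCells()] on every scene, matches against ground truth at
#' the given IoU threshold, and pools the counts.
#'
#' @param model an [RBCDetector-class].
#' @param scenes list of [BloodCellScene-class] objects.
#' @param iou_threshold match threshold.
#' @param ... passed to [detectCells()].
#' @return list with pooled `metrics`, total `tp`/`fp`/`fn`, and the
#'   per-scene detection list.
#' @export
evaluateDetector <- function(model, scenes, iou_threshold = 0.5, ...) {
  tp <- fp <- fn <- 0
  dets <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    d <- detectCells(model, sceneImage(scenes[[i]]), ...)
    mt <- matchDetections(d, sceneBoxes(scenes[[i]]), iou_threshold)
    tp <- tp + mt$tp; fp <- fp + mt$fp; fn <- fn + mt$fn
    dets[[i]] <- d
  }
  list(metrics = computeMetrics(list(tp = tp, fp = fp, fn = fn)),
       tp = tp, fp = fp, fn = fn, detections = dets)
}
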