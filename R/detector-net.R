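## The learned part of the detector: a small convolutional backbone
## (three 3x3 conv + 2x2 max-pool stages, overall stride 8), a region
## proposal head (per-anchor objectness logit + 4 box-regression
## coefficients), and an RoI head (pooled features -> hidden layer ->
## class logits + per-class box refinement). Forward and backward passes
## run through compiled kernels; optimization is Adam. Everything is plain
## arrays, so a fixed seed gives bit-identical training trajectories.

relu <- function(x) pmax(x, 0)

defaultTrainConfig <- function() {
  list(stride = 8L, scales = c(12, 20, 32), ratios = 1,
       channels = c(8, 16, 32), rpn_channels = 32,
       pool_size = c(4L, 4L), head_hidden = 48L,
       epochs = 12L, lr = 1e-3, lr_decay = 0.3, lr_decay_after = 0.7,
       lambda_loc = 1,
       rpn_pos_iou = 0.7, rpn_neg_iou = 0.3, rpn_batch = 64L,
       roi_batch = 24L, roi_pos_iou = 0.5)
}

nAnchorTypes <- function(config) length(config$scales) * length(config$ratios)

initDetectorParams <- function(config) {
  A <- nAnchorTypes(config)
  ch <- config$channels
  he <- function(kh, kw, ci, co) {
    array(rnorm(kh * kw * ci * co, sd = sqrt(2 / (kh * kw * ci))),
          c(kh, kw, ci, co))
  }
  hd <- as.integer(config$head_hidden)
  ## the RoI head pools the stride-4 feature map (after the second pooling
  ## stage): small cells need finer spatial bins than the stride-8 map has
  fdim <- prod(config$pool_size) * ch[2]
  list(
    w1 = he(3, 3, 1, ch[1]),            b1 = numeric(ch[1]),
    w2 = he(3, 3, ch[1], ch[2]),        b2 = numeric(ch[2]),
    w2b = he(3, 3, ch[2], ch[2]),       b2b = numeric(ch[2]),
    w3 = he(3, 3, ch[2], ch[3]),        b3 = numeric(ch[3]),
    wr = he(3, 3, ch[3], config$rpn_channels),
    br = numeric(config$rpn_channels),
    ws = he(1, 1, config$rpn_channels, A),     bs = numeric(A),
    wb = he(1, 1, config$rpn_channels, 4 * A), bb = numeric(4 * A),
    hw1 = matrix(rnorm(fdim * hd, sd = sqrt(2 / fdim)), fdim, hd),
    hb1 = numeric(hd),
    hwc = matrix(rnorm(hd * 2, sd = sqrt(2 / hd)), hd, 2),
    hbc = numeric(2),
    hwb = matrix(rnorm(hd * 8, sd = sqrt(2 / hd)), hd, 8),
    hbb = numeric(8)
  )
}

## forward pass through the backbone + RPN; keeps activations for backward
forwardRPN <- function(x, params) {
  c1 <- conv2d_fw_cpp(x, params$w1, params$b1, 1L); a1 <- relu(c1)
  p1 <- maxpool2_fw_cpp(a1)
  c2 <- conv2d_fw_cpp(p1$out, params$w2, params$b2, 1L); a2 <- relu(c2)
  p2 <- maxpool2_fw_cpp(a2)
  c2b <- conv2d_fw_cpp(p2$out, params$w2b, params$b2b, 1L); a2b <- relu(c2b)
  c3 <- conv2d_fw_cpp(a2b, params$w3, params$b3, 1L); a3 <- relu(c3)
  p3 <- maxpool2_fw_cpp(a3)
  cr <- conv2d_fw_cpp(p3$out, params$wr, params$br, 1L); ar <- relu(cr)
  score <- conv2d_fw_cpp(ar, params$ws, params$bs, 0L)
  reg <- conv2d_fw_cpp(ar, params$wb, params$bb, 0L)
  list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
       c2b = c2b, a2b = a2b,
       c3 = c3, a3 = a3, p3 = p3, cr = cr, ar = ar,
       feat = p3$out, head_feat = a2b, score = score, reg = reg)
}

## backward from gradients on the score/regression maps to all parameters
backwardRPN <- function(fw, params, gscore, greg) {
  g <- list()
  bs_ <- conv2d_bw_cpp(fw$ar, params$ws, gscore, 0L)
  bb_ <- conv2d_bw_cpp(fw$ar, params$wb, greg, 0L)
  g$ws <- bs_$gw; g$bs <- bs_$gb; g$wb <- bb_$gw; g$bb <- bb_$gb
  gar <- (bs_$gin + bb_$gin) * (fw$cr > 0)
  br_ <- conv2d_bw_cpp(fw$p3$out, params$wr, gar, 1L)
  g$wr <- br_$gw; g$br <- br_$gb
  gp3 <- maxpool2_bw_cpp(br_$gin, fw$p3$argmax, dim(fw$a3))
  gc3 <- gp3 * (fw$c3 > 0)
  b3_ <- conv2d_bw_cpp(fw$a2b, params$w3, gc3, 1L)
  g$w3 <- b3_$gw; g$b3 <- b3_$gb
  gc2b <- b3_$gin * (fw$c2b > 0)
  b2b_ <- conv2d_bw_cpp(fw$p2$out, params$w2b, gc2b, 1L)
  g$w2b <- b2b_$gw; g$b2b <- b2b_$gb
  gp2 <- maxpool2_bw_cpp(b2b_$gin, fw$p2$argmax, dim(fw$a2))
  gc2 <- gp2 * (fw$c2 > 0)
  b2_ <- conv2d_bw_cpp(fw$p1$out, params$w2, gc2, 1L)
  g$w2 <- b2_$gw; g$b2 <- b2_$gb
  gp1 <- maxpool2_bw_cpp(b2_$gin, fw$p1$argmax, dim(fw$a1))
  gc1 <- gp1 * (fw$c1 > 0)
  b1_ <- conv2d_bw_cpp(fw$x, params$w1, gc1, 1L)
  g$w1 <- b1_$gw; g$b1 <- b1_$gb
  g
}

## RoI head forward on a matrix of pooled feature vectors (one row per RoI)
forwardHead <- function(X, params) {
  h <- X %*% params$hw1
  h <- sweep(h, 2, params$hb1, `+`)
  hr <- relu(h)
  cls <- sweep(hr %*% params$hwc, 2, params$hbc, `+`)
  box <- sweep(hr %*% params$hwb, 2, params$hbb, `+`)
  list(X = X, h = h, hr = hr, cls = cls, box = box)
}

backwardHead <- function(fw, params, gcls, gbox) {
  ghr <- gcls %*% t(params$hwc) + gbox %*% t(params$hwb)
  gh <- ghr * (fw$h > 0)
  list(hwc = t(fw$hr) %*% gcls, hbc = colSums(gcls),
       hwb = t(fw$hr) %*% gbox, hbb = colSums(gbox),
       hw1 = t(fw$X) %*% gh, hb1 = colSums(gh))
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## assign RPN training targets to anchors: positive when IoU with some
## ground-truth box >= pos_iou or when the anchor is the best match of a
## truth box; negative when max IoU <= neg_iou; the rest are ignored
assignAnchorTargets <- function(anchors, gt, pos_iou, neg_iou) {
  n <- nrow(anchors)
  lab <- rep(NA, n)            # 1 pos, 0 neg, NA ignore
  target <- matrix(0, n, 4)
  if (nrow(gt) == 0L) {
    lab[] <- 0
    return(list(label = lab, target = target, gt_index = rep(NA, n)))
  }
  iou <- boxIoU(anchors, gt)
  best <- max.col(iou, ties.method = "first")
  mx <- iou[cbind(seq_len(n), best)]
  lab[mx <= neg_iou] <- 0
  lab[mx >= pos_iou] <- 1
  ## the best anchor of each truth box is positive, provided it overlaps
  ## at all meaningfully (a floor of 0.1 keeps hopeless anchor layouts
  ## diagnosable instead of silently training on junk matches)
  for (j in seq_len(ncol(iou))) {
    b <- which.max(iou[, j])
    if (iou[b, j] >= 0.1) { lab[b] <- 1; best[b] <- j }
  }
  pos <- which(lab == 1)
  if (length(pos))
    target[pos, ] <- encodeBoxes(anchors[pos, , drop = FALSE],
                                 boxMatrix(gt)[best[pos], , drop = FALSE])
  list(label = lab, target = target, gt_index = best)
}

## pad an image on the bottom/right by edge replication to a stride multiple
padToStride <- function(image, stride) {
  m <- nrow(image); n <- ncol(image)
  mp <- ceiling(m / stride) * stride; np <- ceiling(n / stride) * stride
  if (mp == m && np == n) return(image)
  out <- matrix(0, mp, np)
  out[1:m, 1:n] <- image
  if (mp > m) out[(m + 1):mp, 1:n] <- matrix(image[m, ], mp - m, n,
                                             byrow = TRUE)
  if (np > n) out[, (n + 1):np] <- out[, n]
  out
}

## Candidate RoIs for training the head: the truth boxes, jittered copies
## (shift and log-scale noise, so the refinement branch sees the errors it
## must correct), the current RPN's own top proposals (so the head scores
## the distribution it will face at inference), and random background
## boxes. Labels come from the actual IoU with ground truth: >= pos_iou is
## foreground, < neg_iou background, the narrow band in between is
## discarded. The band is kept narrow on purpose: slightly offset boxes
## must learn low scores or they survive as duplicate detections.
sampleHeadRois <- function(gt, image_shape, proposals = NULL,
                           pos_iou = 0.55, neg_iou = 0.45, n_jitter = 2,
                           n_neg = 8, min_side = 6) {
  gtm <- boxMatrix(gt)
  cand <- gtm
  for (i in seq_len(nrow(gtm))) {
    b <- gtm[i, ]; w <- b[3] - b[1]; h <- b[4] - b[2]
    for (k in seq_len(n_jitter)) {
      sc <- exp(runif(2, -0.2, 0.2))
      cx <- (b[1] + b[3]) / 2 + runif(1, -0.2, 0.2) * w
      cy <- (b[2] + b[4]) / 2 + runif(1, -0.2, 0.2) * h
      cand <- rbind(cand, c(cx - w * sc[1] / 2, cy - h * sc[2] / 2,
                            cx + w * sc[1] / 2, cy + h * sc[2] / 2))
    }
    ## hard negatives: offset copies landing in the 0.1-0.45 IoU band,
    ## the regime where confident false positives live
    for (k in seq_len(n_jitter)) {
      sc <- exp(runif(2, -0.35, 0.35))
      cx <- (b[1] + b[3]) / 2 + sample(c(-1, 1), 1) * runif(1, 0.3, 0.6) * w
      cy <- (b[2] + b[4]) / 2 + sample(c(-1, 1), 1) * runif(1, 0.3, 0.6) * h
      cand <- rbind(cand, c(cx - w * sc[1] / 2, cy - h * sc[2] / 2,
                            cx + w * sc[1] / 2, cy + h * sc[2] / 2))
    }
  }
  if (!is.null(proposals) && nrow(proposals)) cand <- rbind(cand, proposals)
  tries <- 0; found <- 0
  while (found < n_neg && tries < 20 * n_neg) {
    tries <- tries + 1
    s <- runif(1, min_side, min(image_shape) / 2)
    x0 <- runif(1, 0, image_shape[2] - s)
    y0 <- runif(1, 0, image_shape[1] - s)
    bg <- c(x0, y0, x0 + s, y0 + s)
    mx <- if (nrow(gtm)) max(boxIoU(matrix(bg, 1), gtm)) else 0
    if (mx < 0.3) { cand <- rbind(cand, bg); found <- found + 1 }
  }
  cand <- clipBoxes(cand, image_shape)
  ok <- (cand[, 3] - cand[, 1]) >= 2 & (cand[, 4] - cand[, 2]) >= 2
  cand <- cand[ok, , drop = FALSE]
  iou <- boxIoU(cand, gtm)
  best <- max.col(iou, ties.method = "first")
  mx <- iou[cbind(seq_len(nrow(cand)), best)]
  label <- ifelse(mx >= pos_iou, 1L, ifelse(mx < neg_iou, 0L, NA_integer_))
  keep <- !is.na(label)
  list(rois = cand[keep, , drop = FALSE], label = label[keep],
       gt_index = best[keep])
}

## decode the current RPN outputs of one image into its top proposals
rpnProposals <- function(fw, anchors, image_shape, topN = 16,
                         nms_iou = 0.7) {
  gdim <- attr(anchors, "grid")
  hw <- gdim[1] * gdim[2]
  n <- nrow(anchors)
  cell <- (seq_len(n) - 1) %% hw
  atype <- (seq_len(n) - 1) %/% hw
  regv <- as.vector(fw$reg)
  reg <- vapply(0:3, function(k) regv[cell + hw * (4 * atype + k) + 1],
                numeric(n))
  boxes <- decodeBoxes(anchors, reg)
  scores <- sigmoid(as.vector(fw$score))
  fp <- filterProposals(boxes, scores, image_shape,
                        proposalConfig(min_size = 4))
  nm <- nmsBoxes(fp$boxes, fp$scores, nms_iou, topN)
  list(boxes = nm$boxes, scores = nm$scores)
}

#' Train the region-proposal RBC detector
#'
#' Trains the small convolutional backbone and region-proposal head
#' end-to-end on synthetic (or otherwise annotated) scenes, and the RoI
#' classification/refinement head on pooled features. Anchor targets are
#' assigned by IoU (positive at or above `rpn_pos_iou` or as the best
#' anchor of a truth box, negative at or below `rpn_neg_iou`, the rest
#' ignored); a balanced sample of anchors is drawn per image, and the
#' multi-task objective (cross-entropy + smooth-L1, see [multitaskLoss()])
#' is minimized with Adam. The run is deterministic for a fixed seed and
#' dataset: two runs give identical loss trajectories.
#'
#' @param scenes list of [BloodCellScene-class] objects (or lists with
#'   `image` and `boxes`), each with at least one box overall.
#' @param config named list overriding the default training configuration
#'   (epochs, lr, anchor scales/ratios, stride, IoU thresholds, batch
#'   sizes).
#' @param seed integer seed controlling initialization and sampling.
#' @param verbose print per-epoch losses?
#' @return an [RBCDetector-class] model.
#' @export
trainDetector <- function(scenes, config = list(), seed = 1,
                          verbose = FALSE) {
  cfg <- utils::modifyList(defaultTrainConfig(), config)
  if (length(scenes) == 0L) stop("no training scenes")
  getImg <- function(s) if (is(s, "BloodCellScene")) sceneImage(s) else s$image
  getBox <- function(s) if (is(s, "BloodCellScene")) sceneBoxes(s) else s$boxes
  if (sum(vapply(scenes, function(s) nrow(getBox(s)), integer(1))) == 0L)
    stop("training set contains no ground-truth boxes")
  withSeed(seed, {
    params <- initDetectorParams(cfg)
    opt <- adamInit(params)
    A <- nAnchorTypes(cfg)
    anchorCache <- list()
    lossRows <- NULL
    anyPos <- FALSE
    for (ep in seq_len(cfg$epochs)) {
      ## step-decayed learning rate for the late fine-tuning epochs
      lr <- cfg$lr * if (ep > ceiling(cfg$lr_decay_after * cfg$epochs))
        cfg$lr_decay else 1
      epLoss <- c()
      for (si in seq_along(scenes)) {
        img <- padToStride(getImg(scenes[[si]]), cfg$stride)
        gt <- getBox(scenes[[si]])
        key <- paste(dim(img), collapse = "x")
        if (is.null(anchorCache[[key]]))
          anchorCache[[key]] <- generateAnchors(dim(img), cfg$stride,
                                               cfg$scales, cfg$ratios)
        anchors <- anchorCache[[key]]
        x <- array(img, c(dim(img), 1))
        fw <- forwardRPN(x, params)
        gdim <- attr(anchors, "grid")
        tg <- assignAnchorTargets(anchors, gt, cfg$rpn_pos_iou,
                                  cfg$rpn_neg_iou)
        pos <- which(tg$label == 1); neg <- which(tg$label == 0)
        if (length(pos)) anyPos <- TRUE
        npos <- min(length(pos), cfg$rpn_batch %/% 2)
        nneg <- min(length(neg), cfg$rpn_batch - npos)
        sel_pos <- if (npos) sample(pos, npos) else integer(0)
        sel_neg <- if (nneg) sample(neg, nneg) else integer(0)
        sel <- c(sel_pos, sel_neg)
        y <- c(rep(1, npos), rep(0, nneg))
        sv <- as.vector(fw$score)
        p <- sigmoid(sv[sel])
        clsLoss <- -mean(y * log(pmax(p, 1e-12)) +
                         (1 - y) * log(pmax(1 - p, 1e-12)))
        gscore <- array(0, dim(fw$score))
        gscore[sel] <- (p - y) / length(sel)
        ## regression on positives; reg map layout: [h, w, 4A] with the
        ## coefficient order (tx, ty, tw, th) per anchor type
        greg <- array(0, dim(fw$reg))
        locLoss <- 0
        if (npos) {
          hw <- gdim[1] * gdim[2]
          cell <- (sel_pos - 1) %% hw          # lattice position
          atype <- (sel_pos - 1) %/% hw        # anchor type, 0-based
          regv <- as.vector(fw$reg)
          idx4 <- sapply(0:3, function(k) cell + hw * (4 * atype + k) + 1)
          idx4 <- matrix(idx4, npos, 4)
          pred <- matrix(regv[idx4], npos, 4)
          targ <- tg$target[sel_pos, , drop = FALSE]
          err <- pred - targ
          locLoss <- sum(smoothL1(err)) / npos
          gl <- ifelse(abs(err) < 1, err, sign(err)) / npos * cfg$lambda_loc
          greg[idx4] <- gl
        }
        grads <- backwardRPN(fw, params, gscore, greg)
        up <- adamStep(params, grads, opt, lr)
        params <- up$params; opt <- up$state
        ## RoI head step on pooled (fixed) features
        headLoss <- 0
        if (nrow(gt)) {
          props <- if (ep > 1) rpnProposals(fw, anchors, dim(img))$boxes else
            NULL
          hr <- sampleHeadRois(gt, dim(img), proposals = props)
          pooled <- roiPool(fw$head_feat, hr$rois, cfg$pool_size,
                            2 / cfg$stride)
          X <- matrix(pooled, nrow(hr$rois),
                      prod(cfg$pool_size) * cfg$channels[2])
          hf <- forwardHead(X, params)
          nn <- nrow(X)
          z <- hf$cls - apply(hf$cls, 1, max)
          sm <- exp(z) / rowSums(exp(z))
          tgt <- hr$label + 1L                # col 1 background, col 2 rbc
          headLoss <- -mean(log(pmax(sm[cbind(seq_len(nn), tgt)], 1e-12)))
          gcls <- sm
          gcls[cbind(seq_len(nn), tgt)] <- gcls[cbind(seq_len(nn), tgt)] - 1
          gcls <- gcls / nn
          ## box refinement for foreground RoIs (slots 5:8 = class rbc)
          gbox <- matrix(0, nn, 8)
          fg <- which(hr$label == 1L)
          if (length(fg)) {
            bt <- encodeBoxes(hr$rois[fg, , drop = FALSE],
                              boxMatrix(gt)[hr$gt_index[fg], , drop = FALSE])
            errh <- hf$box[fg, 5:8, drop = FALSE] - bt
            headLoss <- headLoss + cfg$lambda_loc *
              sum(smoothL1(errh)) / length(fg)
            gbox[fg, 5:8] <- ifelse(abs(errh) < 1, errh, sign(errh)) /
              length(fg) * cfg$lambda_loc
          }
          hg <- backwardHead(hf, params, gcls, gbox)
          up <- adamStep(params, hg, opt, lr)
          params <- up$params; opt <- up$state
        }
        epLoss <- c(epLoss, clsLoss + cfg$lambda_loc * locLoss + headLoss)
      }
      lossRows <- rbind(lossRows, data.frame(epoch = ep,
                                             loss = mean(epLoss)))
      if (verbose)
        message(sprintf("epoch %d: mean loss %.4f", ep, mean(epLoss)))
    }
    if (!anyPos)
      stop("no positive anchors at the configured scales; ",
           "check anchor scales against the object sizes")
    new("RBCDetector", params = params, config = cfg,
        lossLog = lossRows, version = "rbcdetect-ckpt-1")
  })
}

#' Detect red blood cells in an image
#'
#' Runs the full inference pipeline: backbone and region-proposal forward
#' pass, box-regression decoding of every anchor, proposal clipping / size
#' filtering / ranking ([filterProposals()]), greedy NMS, RoI pooling and
#' the classification head, per-class box refinement, a final per-class
#' NMS, and the score threshold. Deterministic: the same image always
#' yields the same detections.
#'
#' @param model a trained [RBCDetector-class].
#' @param image numeric matrix in \[0, 1\].
#' @param config a [proposalConfig()] list.
#' @param score_threshold minimum foreground probability of a reported
#'   detection.
#' @param final_nms_iou IoU threshold of the per-class NMS on refined
#'   boxes.
#' @param rgi_filter apply the post-network RGI filter
#'   ([rgiRegionFilter()]) to the surviving detections? On by default;
#'   disable for raw network output.
#' @param rgi_threshold minimum center-disc RGI when `rgi_filter` is on.
#' @return detection data.frame (see [detectionTable()]), ordered by
#'   descending score.
#' @export
detectCells <- function(model, image, config = proposalConfig(),
                        score_threshold = 0.5, final_nms_iou = 0.3,
                        rgi_filter = TRUE, rgi_threshold = 0) {
  cfg <- model@config
  if (min(dim(image)) < cfg$stride) stop("image smaller than one stride")
  img <- padToStride(image, cfg$stride)
  x <- array(img, c(dim(img), 1))
  fw <- forwardRPN(x, model@params)
  anchors <- generateAnchors(dim(img), cfg$stride, cfg$scales, cfg$ratios)
  gdim <- attr(anchors, "grid")
  scores <- sigmoid(as.vector(fw$score))
  hw <- gdim[1] * gdim[2]
  n <- nrow(anchors)
  cell <- (seq_len(n) - 1) %% hw
  atype <- (seq_len(n) - 1) %/% hw
  regv <- as.vector(fw$reg)
  reg <- vapply(0:3, function(k) regv[cell + hw * (4 * atype + k) + 1],
                numeric(n))
  boxes <- decodeBoxes(anchors, reg)
  fp <- filterProposals(boxes, scores, dim(image), config)
  nm <- nmsBoxes(fp$boxes, fp$scores, config$nms_iou, config$post_nms_topN)
  if (nrow(nm$boxes) == 0L) return(detectionTable(matrix(numeric(0), 0, 4)))
  headPass <- function(rois) {
    pooled <- roiPool(fw$head_feat, rois, cfg$pool_size, 2 / cfg$stride)
    X <- matrix(pooled, nrow(rois), prod(cfg$pool_size) * cfg$channels[2])
    hf <- forwardHead(X, model@params)
    z <- hf$cls - apply(hf$cls, 1, max)
    sm <- exp(z) / rowSums(exp(z))
    list(prob = sm[, 2], delta = hf$box[, 5:8, drop = FALSE])
  }
  ## iterated refinement: each pass re-pools the current boxes, so
  ## near-duplicate proposals converge onto the same box (and are then
  ## suppressed by NMS) and the final score reflects the box actually
  ## reported
  refined <- nm$boxes
  for (pass in 1:2) {
    h <- headPass(refined)
    refined <- clipBoxes(decodeBoxes(refined, h$delta), dim(image))
    ok <- (refined[, 3] - refined[, 1]) > 0 &
          (refined[, 4] - refined[, 2]) > 0
    refined <- refined[ok, , drop = FALSE]
    if (nrow(refined) == 0L)
      return(detectionTable(matrix(numeric(0), 0, 4)))
  }
  h2 <- headPass(refined)
  fin <- nmsBoxes(refined, h2$prob, final_nms_iou)
  keep <- fin$scores >= score_threshold
  det <- detectionTable(fin$boxes[keep, , drop = FALSE], fin$scores[keep],
                        "rbc")
  if (rgi_filter && nrow(det)) det <- rgiRegionFilter(image, det,
                                                      rgi_threshold)
  det
}

#' Save and load detector checkpoints
#'
#' Checkpoints are RDS files holding a versioned list (`version`,
#' `params`, `config`, `lossLog`); `loadDetector` validates the version
#' tag before reconstructing the model object.
#'
#' @param model an [RBCDetector-class].
#' @param path checkpoint path (`.rds`).
#' @return `saveDetector` returns `path` invisibly; `loadDetector` the
#'   model.
#' @export
saveDetector <- function(model, path) {
  saveRDS(list(version = model@version, params = model@params,
               config = model@config, lossLog = model@lossLog), path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "rbcdetect-ckpt-1"))
    stop("unrecognized checkpoint version: ", obj$version)
  new("RBCDetector", params = obj$params, config = obj$config,
      lossLog = obj$lossLog, version = obj$version)
}
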