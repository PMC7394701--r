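# Detection subnetwork: residual backbone, feature pyramid (P2..P6,
# strides 4..64, P6 used only for proposals), region proposal network and
# box refinement head.  All widths and anchor scales are config-driven so a
# tiny CPU-trainable variant exists alongside the full-scale defaults.

#' Detector configuration
#'
#' Defaults follow the full-scale design: anchor areas \{32^2..512^2\} one
#' per pyramid level, three aspect ratios per location, SGD with momentum
#' 0.9 and weight decay 1e-4.
#'
#' @param channels named list: stem/c2..c5 backbone widths, fpn pyramid
#'   width.
#' @param anchorAreas per-level anchor areas in px^2 (P2..P6).
#' @param ratios aspect ratios as width:height fractions.
#' @param rpnPosIoU,rpnNegIoU anchor matching thresholds.
#' @param rpnBatch anchors sampled per step (1:1 pos:neg).
#' @param nmsRpn,nmsFinal NMS IoU thresholds for proposals / final boxes.
#' @param topN proposals kept after RPN NMS.
#' @param scoreThr final box score threshold.
#' @param roiMinLevel finest pyramid level used for RoI feature
#'   extraction; 2 is the full-scale assignment, the tiny configuration
#'   adds finer levels (strides 2 and 1) so small phantom objects keep
#'   usable feature resolution.
#' @param lr,momentum,weightDecay SGD settings.
#' @return a `DetectorConfig` list.
#' @export
detectorConfig <- function(channels = list(stem = 8L, c2 = 8L, c3 = 12L,
                                           c4 = 16L, c5 = 16L, fpn = 8L),
                           anchorAreas = c(32, 64, 128, 256, 512)^2,
                           ratios = c(1, 0.5, 2),
                           rpnPosIoU = 0.7, rpnNegIoU = 0.3, rpnBatch = 32L,
                           nmsRpn = 0.7, nmsFinal = 0.5, topN = 200L,
                           scoreThr = 0.5, roiMinLevel = 2L,
                           lr = 0.001, momentum = 0.9, weightDecay = 1e-4) {
  cfg <- list(channels = channels, anchorAreas = anchorAreas,
              ratios = ratios, rpnPosIoU = rpnPosIoU, rpnNegIoU = rpnNegIoU,
              rpnBatch = as.integer(rpnBatch), nmsRpn = nmsRpn,
              nmsFinal = nmsFinal, topN = as.integer(topN),
              scoreThr = scoreThr, roiMinLevel = as.integer(roiMinLevel),
              lr = lr, momentum = momentum,
              weightDecay = weightDecay)
  class(cfg) <- "DetectorConfig"
  cfg
}

#' Tiny CPU-trainable detector configuration
#'
#' Narrow widths and small anchor areas suited to 64 px phantom patches.
#' @param ... overrides passed to [detectorConfig()].
#' @export
tinyDetectorConfig <- function(...) {
  detectorConfig(channels = list(stem = 8L, c2 = 8L, c3 = 8L, c4 = 8L,
                                 c5 = 8L, fpn = 8L),
                 anchorAreas = c(16, 32, 64, 128, 256)^2,
                 topN = 50L, lr = 0.01, nmsFinal = 0.3,
                 roiMinLevel = 0L, ...)
}

# ---- box utilities (0-based, half-open, (x1, y1, x2, y2)) -----------------

#' Pairwise intersection-over-union of two box sets
#' @param a,b n x 4 / m x 4 matrices of (x1, y1, x2, y2).
#' @return n x m IoU matrix.
#' @export
boxIoU <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    iw <- pmax(0, pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1]))
    ih <- pmax(0, pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2]))
    inter <- iw * ih
    out[, j] <- inter / pmax(areaA + areaB[j] - inter, 1e-9)
  }
  out
}

# standard box-delta parameterization
#' @keywords internal
boxEncode <- function(boxes, anchors) {
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  cbind((boxes[, 1] + bw / 2 - anchors[, 1] - aw / 2) / aw,
        (boxes[, 2] + bh / 2 - anchors[, 2] - ah / 2) / ah,
        log(bw / aw), log(bh / ah))
}

#' @keywords internal
boxDecode <- function(deltas, anchors) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  acx <- anchors[, 1] + aw / 2; acy <- anchors[, 2] + ah / 2
  cx <- acx + deltas[, 1] * aw; cy <- acy + deltas[, 2] * ah
  w <- aw * exp(.clamp(deltas[, 3], -6, 6))
  h <- ah * exp(.clamp(deltas[, 4], -6, 6))
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' @keywords internal
clipBoxes <- function(boxes, imgShape) {
  cbind(.clamp(boxes[, 1], 0, imgShape[2]), .clamp(boxes[, 2], 0, imgShape[1]),
        .clamp(boxes[, 3], 0, imgShape[2]), .clamp(boxes[, 4], 0, imgShape[1]))
}

#' Greedy non-maximum suppression
#' @param boxes n x 4 matrix; @param scores length-n; @param iouThr overlap
#'   threshold above which the lower-scored box is suppressed.
#' @return indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iouThr = 0.7) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    ious <- boxIoU(boxes[ord[-1L], , drop = FALSE],
                   boxes[i, , drop = FALSE])[, 1]
    ord <- ord[-1L][ious < iouThr]
  }
  keep
}

#' Generate anchors for one pyramid level
#'
#' Three anchors per feature-map location, centred on location centres.
#' The aspect convention is area-preserving: for ratio r = w:h,
#' w = sqrt(area * r), h = sqrt(area / r), so every anchor at a level has
#' the level's area.
#'
#' @param level pyramid level (2..6; stride 2^level).
#' @param featureShape (h, w) of the level's feature map.
#' @param cfg a [detectorConfig()].
#' @return matrix with columns (x1, y1, x2, y2), 3 rows per location.
#' @export
generateAnchors <- function(level, featureShape, cfg = detectorConfig()) {
  stopifnot(level >= 2L, level <= 6L)
  stride <- 2^level
  area <- cfg$anchorAreas[level - 1L]
  h <- featureShape[1]; w <- featureShape[2]
  cy <- (rep(seq_len(h), times = w) - 0.5) * stride
  cx <- (rep(seq_len(w), each = h) - 0.5) * stride
  out <- vector("list", length(cfg$ratios))
  for (i in seq_along(cfg$ratios)) {
    r <- cfg$ratios[i]
    aw <- sqrt(area * r); ah <- sqrt(area / r)
    out[[i]] <- cbind(cx - aw / 2, cy - ah / 2, cx + aw / 2, cy + ah / 2)
  }
  # interleave so the 3 ratios of one location are consecutive
  n <- h * w
  m <- matrix(0, 3L * n, 4L)
  for (i in 1:3) m[seq(i, 3L * n, 3L), ] <- out[[i]]
  m
}

#' Assign a box to a pyramid level by its scale
#'
#' The standard FPN rule k = clamp(floor(k0 + log2(sqrt(w h)/224)), 2, 5)
#' with k0 = 4: a 224 px box maps to P4, smaller boxes to finer levels.
#'
#' @param box length-4 (x1, y1, x2, y2).
#' @param k0 reference level. @param refSize reference box side in px.
#' @return integer level in 2..5.
#' @export
assignLevel <- function(box, k0 = 4L, refSize = 224, minLevel = 2L,
                        maxLevel = 5L) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  if (w <= 0 || h <= 0) stop("degenerate box")
  as.integer(.clamp(floor(k0 + log2(sqrt(w * h) / refSize)),
                    as.integer(minLevel), as.integer(maxLevel)))
}

# ---- RoIAlign -------------------------------------------------------------

# bilinear gather on a feature map; pixel value located at its 0-based
# integer coordinate.  Returns values plus the corner indices/weights used
# (for the scatter backward).
.bilinearGather <- function(feat, ys, xs) {
  h <- dim(feat)[1]; w <- dim(feat)[2]; C <- dim(feat)[3]
  ys <- .clamp(ys, 0, h - 1); xs <- .clamp(xs, 0, w - 1)
  r0 <- pmin(floor(ys), h - 2L); c0 <- pmin(floor(xs), w - 2L)
  r0 <- pmax(r0, 0L); c0 <- pmax(c0, 0L)
  wr <- ys - r0; wc <- xs - c0
  m <- length(ys); n <- length(xs)
  i00 <- outer(r0 + 1, c0 * h, "+")
  i10 <- i00 + 1
  i01 <- i00 + h
  i11 <- i01 + 1
  w00 <- outer(1 - wr, 1 - wc); w01 <- outer(1 - wr, wc)
  w10 <- outer(wr, 1 - wc); w11 <- outer(wr, wc)
  val <- array(0, c(m, n, C))
  for (ch in seq_len(C)) {
    f <- feat[, , ch]
    val[, , ch] <- w00 * f[i00] + w01 * f[i01] + w10 * f[i10] + w11 * f[i11]
  }
  list(val = val, idx = list(i00, i01, i10, i11),
       wts = list(w00, w01, w10, w11), C = C, h = h, w = w)
}

#' RoIAlign: quantization-free fixed-size feature extraction for a box
#'
#' The box (image px) is mapped onto the level's feature grid by its
#' stride, divided into `outSize` bins, and each bin is averaged over
#' `sampling` x `sampling` bilinear sample points at non-quantized
#' coordinates.
#'
#' @param feat H x W x C feature array of one pyramid level.
#' @param box (x1, y1, x2, y2) in image px.
#' @param stride the level's stride (image px per feature px).
#' @param outSize output spatial size (default 33, the mask FoV size).
#' @param sampling sample points per bin side.
#' @param cacheBwd keep the gather geometry for a backward pass.
#' @return outSize x outSize x C array (with attribute "cache" when
#'   `cacheBwd`).
#' @export
roiAlign <- function(feat, box, stride, outSize = 33L, sampling = 2L,
                     cacheBwd = FALSE) {
  bw <- (box[3] - box[1]) / stride
  bh <- (box[4] - box[2]) / stride
  if (bw <= 0 || bh <= 0) stop("zero-area box")
  ns <- outSize * sampling
  # dense sample grid; block averages of sampling x sampling give the bins
  ys <- box[2] / stride + (seq_len(ns) - 0.5) / ns * bh - 0.5
  xs <- box[1] / stride + (seq_len(ns) - 0.5) / ns * bw - 0.5
  g <- .bilinearGather(feat, ys, xs)
  C <- dim(feat)[3]
  blockAvg <- function(m, k) {
    a <- nrow(m) %/% k; b <- ncol(m) %/% k
    m1 <- matrix(colSums(matrix(m, k)), a, k * b)
    t(matrix(colSums(matrix(t(m1), k)), b, a)) / k^2
  }
  out <- array(0, c(outSize, outSize, C))
  for (ch in seq_len(C))
    out[, , ch] <- blockAvg(g$val[, , ch], sampling)
  if (cacheBwd) attr(out, "cache") <- g
  out
}

# scatter the RoIAlign backward: dOut (s x s x C) -> dFeat (H x W x C)
#' @keywords internal
roiAlignBwd <- function(dOut, cache, sampling = 2L) {
  s <- dim(dOut)[1]; C <- cache$C
  dFeat <- array(0, c(cache$h, cache$w, C))
  for (ch in seq_len(C)) {
    dDense <- (dOut[rep(seq_len(s), each = sampling),
                    rep(seq_len(s), each = sampling), ch]) / sampling^2
    acc <- numeric(cache$h * cache$w)
    for (k in 1:4) {
      iv <- as.vector(cache$idx[[k]])
      wv <- as.vector(cache$wts[[k]]) * as.vector(dDense)
      t <- rowsum(wv, iv)
      acc[as.integer(rownames(t))] <- acc[as.integer(rownames(t))] + t[, 1]
    }
    dFeat[, , ch] <- matrix(acc, cache$h, cache$w)
  }
  dFeat
}

# ---- backbone + FPN -------------------------------------------------------

#' Initialise detector weights
#' @param cfg a [detectorConfig()].
#' @param seed integer RNG seed.
#' @return nested weight list.
#' @export
initDetectorWeights <- function(cfg = tinyDetectorConfig(), seed = 1L) {
  set.seed(seed)
  ch <- cfg$channels; f <- ch$fpn
  w <- list(
    stem = blockInit(3L, 1L, ch$stem),
    d2a = blockInit(3L, ch$stem, ch$c2),   # stride 2
    d2b = blockInit(3L, ch$c2, ch$c2),     # stride 2 -> C2 (stride 4)
    res2 = resInit(ch$c2),
    d3 = blockInit(3L, ch$c2, ch$c3), res3 = resInit(ch$c3),
    d4 = blockInit(3L, ch$c3, ch$c4), res4 = resInit(ch$c4),
    d5 = blockInit(3L, ch$c4, ch$c5), res5 = resInit(ch$c5),
    lat0 = nnConvInit(1L, ch$stem, f), lat1 = nnConvInit(1L, ch$c2, f),
    lat2 = nnConvInit(1L, ch$c2, f), lat3 = nnConvInit(1L, ch$c3, f),
    lat4 = nnConvInit(1L, ch$c4, f), lat5 = nnConvInit(1L, ch$c5, f),
    sm0 = nnConvInit(3L, f, f), sm1 = nnConvInit(3L, f, f),
    sm2 = nnConvInit(3L, f, f), sm3 = nnConvInit(3L, f, f),
    sm4 = nnConvInit(3L, f, f), sm5 = nnConvInit(3L, f, f),
    rpnConv = nnConvInit(3L, f, f),
    rpnCls = nnConvInit(1L, f, 6L),   # 3 anchors x 2 classes
    rpnBox = nnConvInit(1L, f, 12L),  # 3 anchors x 4 deltas
    fc1 = nnFcInit(7L * 7L * f, 64L),
    fcCls = nnFcInit(64L, 2L),
    fcBox = nnFcInit(64L, 4L)
  )
  # prediction heads start near zero (standard detection-head init)
  for (nm in c("rpnCls", "rpnBox", "fcCls", "fcBox"))
    w[[nm]]$W <- w[[nm]]$W * 0.1
  w
}

# pad a 2D image up to a multiple of 64 (edge replication keeps statistics)
#' @keywords internal
padTo64 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  H <- as.integer(ceiling(h / 64) * 64); W <- as.integer(ceiling(w / 64) * 64)
  if (H == h && W == w) return(list(img = img, h = h, w = w))
  out <- matrix(0, H, W)
  out[seq_len(h), seq_len(w)] <- img
  if (H > h) out[(h + 1):H, seq_len(w)] <- matrix(img[h, ], H - h, w,
                                                  byrow = TRUE)
  if (W > w) out[, (w + 1):W] <- out[, w]
  list(img = out, h = h, w = w)
}

# full backbone+FPN forward with caches
#' @keywords internal
fpnForward <- function(img, wts) {
  x <- array(img, c(dim(img), 1L))
  s0 <- blockFwd(x, wts$stem, 1L)
  a <- blockFwd(s0$y, wts$d2a, 2L)
  b <- blockFwd(a$y, wts$d2b, 2L)
  r2 <- resFwd(b$y, wts$res2)           # C2, stride 4
  d3 <- blockFwd(r2$y, wts$d3, 2L); r3 <- resFwd(d3$y, wts$res3)
  d4 <- blockFwd(r3$y, wts$d4, 2L); r4 <- resFwd(d4$y, wts$res4)
  d5 <- blockFwd(r4$y, wts$d5, 2L); r5 <- resFwd(d5$y, wts$res5)
  l0 <- nnConvFwd(s0$y, wts$lat0, pad = 0L)
  l1 <- nnConvFwd(a$y, wts$lat1, pad = 0L)
  l2 <- nnConvFwd(r2$y, wts$lat2, pad = 0L)
  l3 <- nnConvFwd(r3$y, wts$lat3, pad = 0L)
  l4 <- nnConvFwd(r4$y, wts$lat4, pad = 0L)
  l5 <- nnConvFwd(r5$y, wts$lat5, pad = 0L)
  m5 <- l5$y
  m4 <- l4$y + .fitTo(nnUp2Fwd(m5), dim(l4$y)[1], dim(l4$y)[2])
  m3 <- l3$y + .fitTo(nnUp2Fwd(m4), dim(l3$y)[1], dim(l3$y)[2])
  m2 <- l2$y + .fitTo(nnUp2Fwd(m3), dim(l2$y)[1], dim(l2$y)[2])
  m1 <- l1$y + .fitTo(nnUp2Fwd(m2), dim(l1$y)[1], dim(l1$y)[2])
  m0 <- l0$y + .fitTo(nnUp2Fwd(m1), dim(l0$y)[1], dim(l0$y)[2])
  p0 <- nnConvFwd(m0, wts$sm0); p1 <- nnConvFwd(m1, wts$sm1)
  p2 <- nnConvFwd(m2, wts$sm2); p3 <- nnConvFwd(m3, wts$sm3)
  p4 <- nnConvFwd(m4, wts$sm4); p5 <- nnConvFwd(m5, wts$sm5)
  p6 <- nnSub2Fwd(p5$y)
  list(P = list(`0` = p0$y, `1` = p1$y, `2` = p2$y, `3` = p3$y,
                `4` = p4$y, `5` = p5$y, `6` = p6),
       cache = list(s0 = s0, a = a, b = b, r2 = r2, d3 = d3, r3 = r3,
                    d4 = d4, r4 = r4, d5 = d5, r5 = r5,
                    l0 = l0, l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5,
                    p0 = p0, p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5))
}

# backward through FPN + backbone given dP (list "2".."6"); returns grads
#' @keywords internal
fpnBackward <- function(dP, wts, cache) {
  g <- list()
  dP5 <- dP$`5` + nnSub2Bwd(dP$`6`, dim(cache$p5$y))
  b0 <- nnConvBwd(dP$`0`, wts$sm0, cache$p0$cache)
  g$sm0 <- list(W = b0$dW, b = b0$db); dm0 <- b0$dx
  b1 <- nnConvBwd(dP$`1`, wts$sm1, cache$p1$cache)
  g$sm1 <- list(W = b1$dW, b = b1$db)
  dm1 <- b1$dx + nnUp2Bwd(.fitTo(dm0, 2L * dim(b1$dx)[1], 2L * dim(b1$dx)[2]))
  b2 <- nnConvBwd(dP$`2`, wts$sm2, cache$p2$cache)
  g$sm2 <- list(W = b2$dW, b = b2$db)
  dm2 <- b2$dx + nnUp2Bwd(.fitTo(dm1, 2L * dim(b2$dx)[1], 2L * dim(b2$dx)[2]))
  b3 <- nnConvBwd(dP$`3`, wts$sm3, cache$p3$cache)
  g$sm3 <- list(W = b3$dW, b = b3$db)
  dm3 <- b3$dx + nnUp2Bwd(.fitTo(dm2, 2L * dim(b3$dx)[1], 2L * dim(b3$dx)[2]))
  b4 <- nnConvBwd(dP$`4`, wts$sm4, cache$p4$cache)
  g$sm4 <- list(W = b4$dW, b = b4$db)
  dm4 <- b4$dx + nnUp2Bwd(.fitTo(dm3, 2L * dim(b4$dx)[1], 2L * dim(b4$dx)[2]))
  b5 <- nnConvBwd(dP5, wts$sm5, cache$p5$cache)
  g$sm5 <- list(W = b5$dW, b = b5$db)
  dm5 <- b5$dx + nnUp2Bwd(.fitTo(dm4, 2L * dim(b5$dx)[1], 2L * dim(b5$dx)[2]))
  lb0 <- nnConvBwd(dm0, wts$lat0, cache$l0$cache)
  lb1 <- nnConvBwd(dm1, wts$lat1, cache$l1$cache)
  g$lat0 <- list(W = lb0$dW, b = lb0$db); g$lat1 <- list(W = lb1$dW, b = lb1$db)
  lb2 <- nnConvBwd(dm2, wts$lat2, cache$l2$cache)
  lb3 <- nnConvBwd(dm3, wts$lat3, cache$l3$cache)
  lb4 <- nnConvBwd(dm4, wts$lat4, cache$l4$cache)
  lb5 <- nnConvBwd(dm5, wts$lat5, cache$l5$cache)
  g$lat2 <- list(W = lb2$dW, b = lb2$db); g$lat3 <- list(W = lb3$dW, b = lb3$db)
  g$lat4 <- list(W = lb4$dW, b = lb4$db); g$lat5 <- list(W = lb5$dW, b = lb5$db)
  rb5 <- resBwd(lb5$dx, wts$res5, cache$r5$cache); g$res5 <- rb5$g
  db5 <- blockBwd(rb5$dx, wts$d5, cache$d5$cache); g$d5 <- db5$g
  rb4 <- resBwd(lb4$dx + db5$dx, wts$res4, cache$r4$cache); g$res4 <- rb4$g
  db4 <- blockBwd(rb4$dx, wts$d4, cache$d4$cache); g$d4 <- db4$g
  rb3 <- resBwd(lb3$dx + db4$dx, wts$res3, cache$r3$cache); g$res3 <- rb3$g
  db3 <- blockBwd(rb3$dx, wts$d3, cache$d3$cache); g$d3 <- db3$g
  rb2 <- resBwd(lb2$dx + db3$dx, wts$res2, cache$r2$cache); g$res2 <- rb2$g
  bb <- blockBwd(rb2$dx, wts$d2b, cache$b$cache); g$d2b <- bb$g
  ab <- blockBwd(bb$dx + lb1$dx, wts$d2a, cache$a$cache); g$d2a <- ab$g
  sb <- blockBwd(ab$dx + lb0$dx, wts$stem, cache$s0$cache); g$stem <- sb$g
  g
}

#' Build the feature pyramid for one image patch
#'
#' @param imagePatch 2D matrix in [0, 1]; sides not divisible by 64 are
#'   internally padded and the pyramid cropped back consistently.
#' @param weights from [initDetectorWeights()].
#' @return list of feature arrays P2..P6 (named "2".."6"), strides 4..64.
#' @export
buildPyramid <- function(imagePatch, weights) {
  p <- padTo64(imagePatch)
  fp <- fpnForward(p$img, weights)
  if (p$h != nrow(p$img) || p$w != ncol(p$img)) {
    for (lv in names(fp$P)) {
      st <- 2^as.integer(lv)
      fp$P[[lv]] <- fp$P[[lv]][seq_len(ceiling(p$h / st)),
                               seq_len(ceiling(p$w / st)), , drop = FALSE]
    }
  }
  fp$P
}

# RPN head on one level; returns per-anchor logits (n x 2) and deltas (n x 4)
# anchors ordered location-major, 3 ratios consecutive (matches
# generateAnchors)
#' @keywords internal
rpnHeadFwd <- function(P, wts) {
  h <- dim(P)[1]; w <- dim(P)[2]
  c0 <- nnConvFwd(P, wts$rpnConv)
  c1 <- nnReluFwd(c0$y)
  cls <- nnConvFwd(c1$y, wts$rpnCls, pad = 0L)
  reg <- nnConvFwd(c1$y, wts$rpnBox, pad = 0L)
  # feature maps are (h, w, 6/12); locations column-major (row fastest);
  # anchors are (rep over w, each h) column-major too: location index
  # l = r + (c-1)h matches
  n <- h * w
  clsM <- matrix(0, 3L * n, 2L); regM <- matrix(0, 3L * n, 4L)
  for (a in 1:3) {
    clsM[seq(a, 3L * n, 3L), ] <- cbind(as.vector(cls$y[, , 2L * a - 1L]),
                                        as.vector(cls$y[, , 2L * a]))
    for (k in 1:4)
      regM[seq(a, 3L * n, 3L), k] <- as.vector(reg$y[, , 4L * (a - 1L) + k])
  }
  list(cls = clsM, reg = regM,
       cache = list(c0 = c0$cache, relu = c1$cache, cls = cls, reg = reg,
                    h = h, w = w))
}

#' @keywords internal
rpnHeadBwd <- function(dCls, dReg, wts, cache) {
  h <- cache$h; w <- cache$w; n <- h * w
  dClsY <- array(0, c(h, w, 6L)); dRegY <- array(0, c(h, w, 12L))
  for (a in 1:3) {
    rows <- seq(a, 3L * n, 3L)
    dClsY[, , 2L * a - 1L] <- matrix(dCls[rows, 1], h, w)
    dClsY[, , 2L * a] <- matrix(dCls[rows, 2], h, w)
    for (k in 1:4)
      dRegY[, , 4L * (a - 1L) + k] <- matrix(dReg[rows, k], h, w)
  }
  cb <- nnConvBwd(dClsY, wts$rpnCls, cache$cls$cache)
  rb <- nnConvBwd(dRegY, wts$rpnBox, cache$reg$cache)
  dr <- nnReluBwd(cb$dx + rb$dx, cache$relu)
  hb <- nnConvBwd(dr, wts$rpnConv, cache$c0)
  list(dP = hb$dx,
       g = list(rpnConv = list(W = hb$dW, b = hb$db),
                rpnCls = list(W = cb$dW, b = cb$db),
                rpnBox = list(W = rb$dW, b = rb$db)))
}

#' Detector multitask loss
#'
#' Four terms: RPN and R-CNN classification (cross-entropy on class
#' probabilities) plus RPN and R-CNN box regression (smooth-L1, positives
#' only); the total is their sum.  With no positives the box terms are 0.
#'
#' @param pred list: `rpnClsProb` (n x 2 rows summing to 1), `rpnBoxPred`
#'   (npos x 4), `rcnnClsProb` (m x 2), `rcnnBoxPred` (mpos x 4).
#' @param targets list: `rpnCls` (n, values 1 = background, 2 =
#'   foreground), `rpnBox` (npos x 4), `rcnnCls` (m), `rcnnBox` (mpos x 4).
#' @return list with `LclsRpn`, `LboxRpn`, `LclsRcnn`, `LboxRcnn`, `Ltotal`.
#' @export
detectorLoss <- function(pred, targets) {
  ce <- function(p, t) {
    if (is.null(p) || NROW(p) == 0L) return(0)
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), t)], 1e-12)))
  }
  sl1 <- function(x, t) {
    if (is.null(x) || NROW(x) == 0L) return(0)
    nnSmoothL1(matrix(x, ncol = 4), matrix(t, ncol = 4))$loss
  }
  l1 <- ce(pred$rpnClsProb, targets$rpnCls)
  l2 <- sl1(pred$rpnBoxPred, targets$rpnBox)
  l3 <- ce(pred$rcnnClsProb, targets$rcnnCls)
  l4 <- sl1(pred$rcnnBoxPred, targets$rcnnBox)
  list(LclsRpn = l1, LboxRpn = l2, LclsRcnn = l3, LboxRcnn = l4,
       Ltotal = l1 + l2 + l3 + l4)
}

#' Generate scored proposals from the feature pyramid
#'
#' RPN heads run on P2..P6; anchors are shifted by the predicted regression
#' deltas, scored by the foreground softmax probability, clipped to the
#' image and NMS-filtered.
#'
#' @param pyramid from [buildPyramid()].
#' @param weights detector weights.
#' @param imgShape (H, W) of the source image.
#' @param cfg a [detectorConfig()].
#' @return data.frame (x1, y1, x2, y2, score), up to `cfg$topN` rows.
#' @export
proposeBoxes <- function(pyramid, weights, imgShape,
                         cfg = tinyDetectorConfig()) {
  allBoxes <- NULL; allScores <- NULL
  for (lv in 2:6) {
    P <- pyramid[[as.character(lv)]]
    head <- rpnHeadFwd(P, weights)
    anchors <- generateAnchors(lv, dim(P)[1:2], cfg)
    sm <- exp(head$cls - apply(head$cls, 1, max))
    prob <- sm[, 2] / rowSums(sm)
    boxes <- boxDecode(head$reg, anchors)
    allBoxes <- rbind(allBoxes, boxes)
    allScores <- c(allScores, prob)
  }
  allBoxes <- clipBoxes(allBoxes, imgShape)
  ok <- which(allBoxes[, 3] - allBoxes[, 1] >= 2 &
                allBoxes[, 4] - allBoxes[, 2] >= 2)
  allBoxes <- allBoxes[ok, , drop = FALSE]; allScores <- allScores[ok]
  # pre-NMS cap for speed
  if (length(allScores) > 600L) {
    top <- order(allScores, decreasing = TRUE)[1:600]
    allBoxes <- allBoxes[top, , drop = FALSE]; allScores <- allScores[top]
  }
  keep <- nms(allBoxes, allScores, cfg$nmsRpn)
  keep <- head(keep, cfg$topN)
  data.frame(x1 = allBoxes[keep, 1], y1 = allBoxes[keep, 2],
             x2 = allBoxes[keep, 3], y2 = allBoxes[keep, 4],
             score = allScores[keep])
}

# R-CNN head forward for one RoI; returns class prob, deltas, caches
#' @keywords internal
rcnnHeadFwd <- function(pyramid, box, weights, cacheBwd = FALSE,
                        minLevel = 2L) {
  lv <- assignLevel(box, minLevel = minLevel)
  feat <- roiAlign(pyramid[[as.character(lv)]], box, 2^lv, outSize = 7L,
                   cacheBwd = cacheBwd)
  x <- as.vector(feat)
  f1 <- nnFcFwd(x, weights$fc1)
  r1 <- nnReluFwd(f1$y)
  cls <- nnFcFwd(r1$y, weights$fcCls)
  bx <- nnFcFwd(r1$y, weights$fcBox)
  e <- exp(cls$y - max(cls$y))
  list(prob = as.vector(e / sum(e)), deltas = as.vector(bx$y), level = lv,
       cache = if (cacheBwd) list(feat = feat, f1 = f1, r1 = r1$cache,
                                  cls = cls, bx = bx) else NULL)
}

#' Detect mitochondrion boxes on one slice
#'
#' Full detection pass: pyramid, RPN proposals, R-CNN scoring and box
#' refinement, final NMS.
#'
#' @param image 2D matrix in [0, 1].
#' @param weights detector weights.
#' @param cfg a [detectorConfig()].
#' @param sliceIndex stored in the output.
#' @return data.frame (x1, y1, x2, y2, score, slice).
#' @export
predictBoxes <- function(image, weights, cfg = tinyDetectorConfig(),
                         sliceIndex = 0L) {
  pyr <- buildPyramid(image, weights)
  props <- proposeBoxes(pyr, weights, dim(image), cfg)
  if (nrow(props) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0),
                      slice = integer(0)))
  out <- matrix(0, nrow(props), 5L)
  for (i in seq_len(nrow(props))) {
    b <- as.numeric(props[i, 1:4])
    r <- rcnnHeadFwd(pyr, b, weights, minLevel = cfg$roiMinLevel)
    rb <- boxDecode(matrix(r$deltas, 1L), matrix(b, 1L))
    out[i, ] <- c(clipBoxes(rb, dim(image)), r$prob[2])
  }
  keepScore <- out[, 5] >= cfg$scoreThr &
    (out[, 3] - out[, 1]) >= 2 & (out[, 4] - out[, 2]) >= 2
  out <- out[keepScore, , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0),
                      slice = integer(0)))
  keep <- nms(out[, 1:4, drop = FALSE], out[, 5], cfg$nmsFinal)
  data.frame(x1 = out[keep, 1], y1 = out[keep, 2], x2 = out[keep, 3],
             y2 = out[keep, 4], score = out[keep, 5],
             slice = rep(as.integer(sliceIndex), length(keep)))
}

# ---- training -------------------------------------------------------------

# match anchors to ground-truth boxes; returns sampled indices and targets
#' @keywords internal
rpnTargets <- function(anchors, gt, cfg) {
  n <- nrow(anchors)
  lab <- rep(0L, n)            # 0 ignore, 1 bg, 2 fg
  matched <- integer(n)
  if (nrow(gt) > 0L) {
    iou <- boxIoU(anchors, gt)
    best <- apply(iou, 1, max)
    matched <- apply(iou, 1, which.max)
    lab[best < cfg$rpnNegIoU] <- 1L
    lab[best >= cfg$rpnPosIoU] <- 2L
    for (j in seq_len(nrow(gt))) {   # best anchor per gt is always positive
      mj <- max(iou[, j])
      if (mj > 1e-6) lab[which(iou[, j] >= mj - 1e-9)] <- 2L
    }
  } else lab[] <- 1L
  pos <- which(lab == 2L); neg <- which(lab == 1L)
  nPos <- min(length(pos), cfg$rpnBatch %/% 2L)
  if (length(pos) > nPos) pos <- sample(pos, nPos)
  nNeg <- min(length(neg), cfg$rpnBatch - nPos)
  if (length(neg) > nNeg) neg <- sample(neg, nNeg)
  boxT <- if (length(pos) > 0L)
    boxEncode(gt[matched[pos], , drop = FALSE], anchors[pos, , drop = FALSE])
  else NULL
  list(pos = pos, neg = neg, boxTargets = boxT, matched = matched)
}

# jitter a ground-truth box by up to +-25% shift/scale (training proposals)
#' @keywords internal
jitterBox <- function(box, frac = 0.25) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  cx <- (box[1] + box[3]) / 2 + runif(1, -frac, frac) * w
  cy <- (box[2] + box[4]) / 2 + runif(1, -frac, frac) * h
  w2 <- w * exp(runif(1, log(1 - frac), log(1 + frac)))
  h2 <- h * exp(runif(1, log(1 - frac), log(1 + frac)))
  c(cx - w2 / 2, cy - h2 / 2, cx + w2 / 2, cy + h2 / 2)
}

#' One SGD training step of the detection subnetwork
#'
#' RPN anchors are matched at IoU thresholds (`rpnPosIoU`/`rpnNegIoU`) and
#' sampled 1:1; R-CNN trains on jittered ground-truth boxes (positives)
#' plus random background boxes.  Returns the four loss terms and updated
#' weights/optimiser state.
#'
#' @param image 2D matrix; @param gtBoxes k x 4 matrix of ground-truth
#'   boxes; @param weights,state,cfg current weights, SGD state, config.
#' @return list(weights, state, loss).
#' @export
detectorTrainStep <- function(image, gtBoxes, weights, state,
                              cfg = tinyDetectorConfig()) {
  p <- padTo64(image)
  fp <- fpnForward(p$img, weights)
  imgShape <- dim(p$img)
  g <- list()
  dP <- lapply(fp$P, function(x) array(0, dim(x)))

  # --- RPN over all levels
  lossCls <- 0; lossBox <- 0
  heads <- list()
  anchorsL <- list()
  for (lv in 2:6) {
    P <- fp$P[[as.character(lv)]]
    heads[[as.character(lv)]] <- rpnHeadFwd(P, weights)
    anchorsL[[as.character(lv)]] <- generateAnchors(lv, dim(P)[1:2], cfg)
  }
  counts <- vapply(anchorsL, nrow, 0L)
  anchors <- do.call(rbind, anchorsL)
  clsAll <- do.call(rbind, lapply(heads, `[[`, "cls"))
  regAll <- do.call(rbind, lapply(heads, `[[`, "reg"))
  tg <- rpnTargets(anchors, gtBoxes, cfg)
  sel <- c(tg$pos, tg$neg)
  dCls <- matrix(0, nrow(clsAll), 2L)
  dReg <- matrix(0, nrow(regAll), 4L)
  if (length(sel) > 0L) {
    t2 <- c(rep(2L, length(tg$pos)), rep(1L, length(tg$neg)))
    ceo <- nnSoftmaxCE(clsAll[sel, , drop = FALSE], t2)
    lossCls <- ceo$loss
    dCls[sel, ] <- ceo$dlogits
  }
  if (length(tg$pos) > 0L) {
    slo <- nnSmoothL1(regAll[tg$pos, , drop = FALSE], tg$boxTargets)
    lossBox <- slo$loss
    dReg[tg$pos, ] <- slo$dx
  }
  off <- 0L
  for (lv in 2:6) {
    k <- as.character(lv)
    idx <- off + seq_len(counts[[k]])
    hb <- rpnHeadBwd(dCls[idx, , drop = FALSE], dReg[idx, , drop = FALSE],
                     weights, heads[[k]]$cache)
    dP[[k]] <- dP[[k]] + hb$dP
    g <- if (length(g) == 0L) hb$g else addGrads(g, hb$g)
    off <- off + counts[[k]]
  }

  # --- R-CNN on jittered GT (guaranteed positives) plus the RPN's own
  # proposals labeled by IoU, so the refinement head sees hard negatives
  lossClsR <- 0; lossBoxR <- 0
  rois <- list(); roiT <- integer(0); roiGt <- list()
  if (nrow(gtBoxes) > 0L) {
    for (j in seq_len(nrow(gtBoxes))) for (r in 1:2) {
      b <- clipBoxes(matrix(jitterBox(gtBoxes[j, ]), 1L), imgShape)
      if (b[3] - b[1] < 3 || b[4] - b[2] < 3) next
      rois[[length(rois) + 1L]] <- as.numeric(b)
      roiT <- c(roiT, 2L); roiGt[[length(roiGt) + 1L]] <- gtBoxes[j, ]
    }
  }
  # decode current proposals from the already-computed RPN outputs
  sm <- exp(clsAll - apply(clsAll, 1, max))
  fgProb <- sm[, 2] / rowSums(sm)
  top <- order(fgProb, decreasing = TRUE)[seq_len(min(150L, length(fgProb)))]
  props <- clipBoxes(boxDecode(regAll[top, , drop = FALSE],
                               anchors[top, , drop = FALSE]), imgShape)
  okP <- which(props[, 3] - props[, 1] >= 3 & props[, 4] - props[, 2] >= 3)
  if (length(okP) > 0L) {
    props <- props[okP, , drop = FALSE]
    keepP <- nms(props, fgProb[top][okP], cfg$nmsRpn)
    keepP <- head(keepP, 10L)
    for (pi in keepP) {
      b <- props[pi, ]
      if (nrow(gtBoxes) > 0L) {
        ious <- boxIoU(matrix(b, 1L), gtBoxes)[1, ]
        j <- which.max(ious)
        if (ious[j] >= 0.5) {
          rois[[length(rois) + 1L]] <- as.numeric(b)
          roiT <- c(roiT, 2L)
          roiGt[[length(roiGt) + 1L]] <- gtBoxes[j, ]
          next
        }
        if (ious[j] >= 0.3) next   # ambiguous: skip
      }
      rois[[length(rois) + 1L]] <- as.numeric(b)
      roiT <- c(roiT, 1L); roiGt[length(roiGt) + 1L] <- list(NULL)
    }
  }
  for (r in 1:2) {  # random background boxes of varied size
    s <- runif(1, 8, 0.9 * min(imgShape))
    x1 <- runif(1, 0, imgShape[2] - s); y1 <- runif(1, 0, imgShape[1] - s)
    b <- c(x1, y1, x1 + s, y1 + s)
    if (nrow(gtBoxes) > 0L && max(boxIoU(matrix(b, 1L), gtBoxes)) > 0.3) next
    rois[[length(rois) + 1L]] <- b
    roiT <- c(roiT, 1L); roiGt[length(roiGt) + 1L] <- list(NULL)
  }
  gFc <- NULL
  if (length(rois) > 0L) {
    nR <- length(rois)
    for (i in seq_len(nR)) {
      b <- rois[[i]]
      hf <- rcnnHeadFwd(fp$P, b, weights, cacheBwd = TRUE,
                        minLevel = cfg$roiMinLevel)
      ceo <- nnSoftmaxCE(matrix(log(pmax(hf$prob, 1e-12)), 1L), roiT[i])
      lossClsR <- lossClsR + ceo$loss / nR
      dLogits <- ceo$dlogits / nR
      dDeltas <- matrix(0, 1L, 4L)
      if (roiT[i] == 2L) {
        tgt <- boxEncode(matrix(roiGt[[i]], 1L), matrix(b, 1L))
        slo <- nnSmoothL1(matrix(hf$deltas, 1L), tgt)
        lossBoxR <- lossBoxR + slo$loss / nR
        dDeltas <- slo$dx / nR
      }
      cb <- nnFcBwd(dLogits, weights$fcCls, hf$cache$cls$cache)
      bb <- nnFcBwd(dDeltas, weights$fcBox, hf$cache$bx$cache)
      dR1 <- nnReluBwd(cb$dx + bb$dx, hf$cache$r1)
      fb <- nnFcBwd(dR1, weights$fc1, hf$cache$f1$cache)
      gi <- list(fc1 = list(W = fb$dW, b = fb$db),
                 fcCls = list(W = cb$dW, b = cb$db),
                 fcBox = list(W = bb$dW, b = bb$db))
      gFc <- if (is.null(gFc)) gi else addGrads(gFc, gi)
      dFeat <- roiAlignBwd(array(fb$dx, c(7L, 7L, dim(hf$cache$feat)[3])),
                           attr(hf$cache$feat, "cache"))
      k <- as.character(hf$level)
      dP[[k]] <- dP[[k]] + dFeat
    }
  }
  if (!is.null(gFc)) g <- addGrads2(g, gFc)

  gBack <- fpnBackward(dP, weights, fp$cache)
  g <- addGrads2(g, gBack)
  g <- clipGrads(g, 5)
  up <- sgdStep(weights, g, state, cfg$lr, cfg$momentum, cfg$weightDecay)
  loss <- list(LclsRpn = lossCls, LboxRpn = lossBox, LclsRcnn = lossClsR,
               LboxRcnn = lossBoxR,
               Ltotal = lossCls + lossBox + lossClsR + lossBoxR)
  list(weights = up$weights, state = up$state, loss = loss)
}

# merge two grad lists with disjoint or overlapping names
#' @keywords internal
addGrads2 <- function(a, b) {
  if (is.null(a) || length(a) == 0L) return(b)
  for (nm in names(b))
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else addGrads(a[[nm]], b[[nm]])
  a
}

#' Train the detection subnetwork
#'
#' @param samples list of `list(image =, boxes = k x 4 matrix)` training
#'   patches.
#' @param cfg a [detectorConfig()].
#' @param steps SGD steps (one random sample per step).
#' @param seed RNG seed.
#' @param weights optional warm-start weights.
#' @param verboseEvery print running loss every n steps (0 = silent).
#' @return list(weights, lossTrace).
#' @export
trainMitoDetector <- function(samples, cfg = tinyDetectorConfig(),
                              steps = 300L, seed = 1L, weights = NULL,
                              verboseEvery = 0L) {
  set.seed(seed)
  if (is.null(weights)) weights <- initDetectorWeights(cfg, seed)
  state <- sgdInit(weights)
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    i <- if (length(samples) == 1L) 1L else sample(length(samples), 1L)
    r <- detectorTrainStep(samples[[i]]$image, samples[[i]]$boxes,
                           weights, state, cfg)
    weights <- r$weights; state <- r$state
    trace[s] <- r$loss$Ltotal
    if (verboseEvery > 0L && s %% verboseEvery == 0L)
      message(sprintf("step %d: L=%.4f", s, mean(tail(trace[1:s], 20))))
  }
  list(weights = weights, lossTrace = trace)
}
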