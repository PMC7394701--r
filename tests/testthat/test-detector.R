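test_that("anchor generation matches the published scales and ratios", {
  cfg <- detectorConfig()
  a2 <- generateAnchors(2L, c(4L, 4L), cfg)
  expect_equal(nrow(a2), 48L)                     # 4*4*3 anchors
  sq <- a2[1, ]                                   # first ratio is 1:1
  expect_equal(sq[3] - sq[1], 32)                 # 32 x 32 at P2
  expect_equal(sq[4] - sq[2], 32)
  # area-preserving 1:2 ratio: w * h = 1024 with h = 2w
  half <- a2[2, ]
  w <- half[3] - half[1]; h <- half[4] - half[2]
  expect_equal(w * h, 1024, tolerance = 1e-9)
  expect_equal(h, 2 * w, tolerance = 1e-9)
  expect_equal(w, sqrt(512), tolerance = 1e-9)    # ~22.6
  # every anchor at a level has the level's area
  areas <- (a2[, 3] - a2[, 1]) * (a2[, 4] - a2[, 2])
  expect_true(all(abs(areas - 1024) < 1e-6))
})

test_that("boxes are assigned to pyramid levels by scale", {
  expect_equal(assignLevel(c(0, 0, 224, 224)), 4L)
  expect_equal(assignLevel(c(0, 0, 32, 32)), 2L)      # clamped low
  expect_equal(assignLevel(c(0, 0, 512, 512)), 5L)    # clamped high
  expect_equal(assignLevel(c(0, 0, 448, 448)), 5L)
  expect_equal(assignLevel(c(0, 0, 112, 112)), 3L)
  expect_error(assignLevel(c(5, 5, 5, 9)), "degenerate")
})

test_that("box delta encode/decode round-trips", {
  set.seed(31)
  anchors <- cbind(runif(20, 0, 40), runif(20, 0, 40), 0, 0)
  anchors[, 3] <- anchors[, 1] + runif(20, 5, 30)
  anchors[, 4] <- anchors[, 2] + runif(20, 5, 30)
  boxes <- anchors + matrix(rnorm(80, 0, 2), 20)
  boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 1)
  boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 1)
  dec <- OrganelleEM:::boxDecode(OrganelleEM:::boxEncode(boxes, anchors),
                                 anchors)
  expect_equal(dec, unname(boxes), tolerance = 1e-6)
  # zero deltas reproduce the anchors
  z <- OrganelleEM:::boxDecode(matrix(0, 20, 4), anchors)
  expect_equal(z, unname(anchors), tolerance = 1e-9)
})

test_that("NMS suppresses duplicates and keeps score order", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(20, 20, 30, 30))
  keep <- nms(b, c(0.9, 0.8, 0.7), 0.7)
  expect_equal(keep, c(1L, 3L))
})

test_that("RoIAlign is exact on constants and affine ramps and matches a
           dense bilinear oracle", {
  cst <- array(3.25, c(8, 8, 2))
  out <- roiAlign(cst, c(2.3, 1.1, 18.7, 21.2), stride = 4, outSize = 5L)
  expect_equal(dim(out), c(5L, 5L, 2L))
  expect_true(all(abs(out - 3.25) < 1e-12))
  # bilinear reproduces an affine ramp exactly (interior box)
  ramp <- array(0, c(16, 16, 1))
  ramp[, , 1] <- outer(seq_len(16), seq_len(16),
                       function(r, c) 2 * r + 3 * c)
  rb <- roiAlign(ramp, c(8.5, 9.2, 40.1, 44.3), stride = 4, outSize = 7L)
  ys <- 9.2 / 4 + (2 * (rep(1:7, each = 2)) - 2 + c(0.25, 0.75)) / 14 *
    (44.3 - 9.2) / 4
  # spot-check the centre against direct bilinear interpolation
  ctr <- rb[4, 4, 1]
  ycn <- 9.2 / 4 + 3.5 / 7 * (44.3 - 9.2) / 4 - 0.5
  xcn <- 8.5 / 4 + 3.5 / 7 * (40.1 - 8.5) / 4 - 0.5
  expect_equal(ctr, 2 * (ycn + 1) + 3 * (xcn + 1), tolerance = 1e-6)
  # random map, random box: dense sample-point oracle
  set.seed(32)
  feat <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  box <- c(10.3, 6.7, 52.9, 40.2)
  got <- roiAlign(feat, box, 4, outSize = 5L)
  ns <- 2L
  bf <- array(0, c(5, 5, 2))
  bh <- (box[4] - box[2]) / 4 / 5; bw <- (box[3] - box[1]) / 4 / 5
  for (ch in 1:2) for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (si in 1:ns) for (sj in 1:ns) {
      y <- box[2] / 4 + (i - 1) * bh + (si - 0.5) / ns * bh - 0.5
      x <- box[1] / 4 + (j - 1) * bw + (sj - 0.5) / ns * bw - 0.5
      y <- min(max(y, 0), 15); x <- min(max(x, 0), 15)
      r0 <- min(max(floor(y), 0), 14); c0 <- min(max(floor(x), 0), 14)
      wr <- y - r0; wc <- x - c0
      f <- feat[, , ch]
      acc <- acc + (1 - wr) * (1 - wc) * f[r0 + 1, c0 + 1] +
        (1 - wr) * wc * f[r0 + 1, c0 + 2] +
        wr * (1 - wc) * f[r0 + 2, c0 + 1] + wr * wc * f[r0 + 2, c0 + 2]
    }
    bf[i, j, ch] <- acc / ns^2
  }
  expect_equal(got, bf, tolerance = 1e-5)
  expect_error(roiAlign(feat, c(5, 5, 5, 9), 4), "zero-area")
})

test_that("feature pyramid has the declared strides and is deterministic", {
  set.seed(33)
  w <- initDetectorWeights(tinyDetectorConfig(), seed = 5)
  img <- matrix(runif(256 * 256), 256)
  t0 <- Sys.time()
  P <- buildPyramid(img, w)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  expect_equal(dim(P$`2`)[1:2], c(64L, 64L))
  expect_equal(dim(P$`3`)[1:2], c(32L, 32L))
  expect_equal(dim(P$`4`)[1:2], c(16L, 16L))
  expect_equal(dim(P$`5`)[1:2], c(8L, 8L))
  expect_equal(dim(P$`6`)[1:2], c(4L, 4L))
  P2 <- buildPyramid(img, w)
  expect_identical(P, P2)
})

test_that("detector loss follows the four-term decomposition", {
  # perfect probabilities and exact boxes give zero loss
  pred <- list(rpnClsProb = cbind(c(0, 1), c(1, 0)),
               rpnBoxPred = matrix(c(0.1, 0.2, 0, 0), 1),
               rcnnClsProb = cbind(0, 1),
               rcnnBoxPred = matrix(0, 1, 4))
  tg <- list(rpnCls = c(2L, 1L),
             rpnBox = matrix(c(0.1, 0.2, 0, 0), 1),
             rcnnCls = 2L, rcnnBox = matrix(0, 1, 4))
  l <- detectorLoss(pred, tg)
  expect_equal(l$Ltotal, 0)
  # uniform 2-class prediction: per-anchor classification term = ln 2
  predU <- list(rpnClsProb = matrix(0.5, 6, 2), rpnBoxPred = NULL,
                rcnnClsProb = NULL, rcnnBoxPred = NULL)
  tgU <- list(rpnCls = rep(1:2, 3), rpnBox = NULL, rcnnCls = NULL,
              rcnnBox = NULL)
  expect_equal(detectorLoss(predU, tgU)$LclsRpn, log(2), tolerance = 1e-12)
  # random batch equals independently recomputed terms
  set.seed(34)
  p1 <- matrix(runif(10), 5, 2); p1 <- p1 / rowSums(p1)
  t1 <- sample(1:2, 5, TRUE)
  b1 <- matrix(rnorm(8), 2); bt <- matrix(rnorm(8), 2)
  lr <- detectorLoss(list(rpnClsProb = p1, rpnBoxPred = b1,
                          rcnnClsProb = p1, rcnnBoxPred = b1),
                     list(rpnCls = t1, rpnBox = bt, rcnnCls = t1,
                          rcnnBox = bt))
  ceExp <- -mean(log(p1[cbind(1:5, t1)]))
  d <- b1 - bt
  slExp <- sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)) / 2
  expect_equal(lr$LclsRpn, ceExp, tolerance = 1e-12)
  expect_equal(lr$LboxRpn, slExp, tolerance = 1e-12)
  expect_equal(lr$Ltotal, 2 * ceExp + 2 * slExp, tolerance = 1e-12)
})

test_that("zero regression deltas leave proposals at their anchors", {
  set.seed(35)
  cfg <- tinyDetectorConfig()
  w <- initDetectorWeights(cfg, seed = 2)
  # force the regression head to output zeros
  w$rpnBox$W[] <- 0; w$rpnBox$b[] <- 0
  img <- matrix(runif(64 * 64), 64)
  pyr <- buildPyramid(img, w)
  props <- proposeBoxes(pyr, w, c(64L, 64L), cfg)
  anchors <- do.call(rbind, lapply(2:6, function(lv)
    generateAnchors(lv, dim(pyr[[as.character(lv)]])[1:2], cfg)))
  anchors <- OrganelleEM:::clipBoxes(anchors, c(64L, 64L))
  # every proposal coincides with some clipped anchor
  pm <- as.matrix(props[, 1:4])
  for (i in seq_len(nrow(pm))) {
    dmin <- min(rowSums(abs(anchors - matrix(pm[i, ], nrow(anchors), 4,
                                             byrow = TRUE))))
    expect_lt(dmin, 1e-6)
  }
})
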