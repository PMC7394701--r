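test_that("seed mask puts one active value at the floor-centre", {
  cfg <- segmenterConfig()
  m <- initSeedMask(cfg)
  expect_equal(sum(m != 0), 1L)
  expect_equal(m[17, 17], 0.95)          # 0-based (16, 16)
  expect_equal(sum(m), cfg$seedValue)
  m32 <- initSeedMask(segmenterConfig(s = 32L, step = c(8, 8)))
  expect_equal(which(m32 != 0, arr.ind = TRUE)[1, ], c(row = 17L, col = 17L))
})

test_that("movement steps scale with the box size and round half away", {
  cfg <- segmenterConfig()
  expect_equal(scaleStep(33, 33, cfg), c(8, 8))
  expect_equal(scaleStep(66, 33, cfg), c(16, 8))
  expect_equal(scaleStep(16.5, 66, cfg), c(4, 16))
  set.seed(41)
  for (i in 1:20) {
    w <- runif(1, 5, 200); h <- runif(1, 5, 200)
    expect_equal(scaleStep(w, h, cfg), c(8 * w / 33, 8 * h / 33),
                 tolerance = 1e-12)
  }
  expect_error(scaleStep(0, 10, cfg), "positive")
  rha <- OrganelleEM:::roundHalfAway
  expect_equal(rha(c(2.5, -2.5, 2.4, -2.4)), c(3, -3, 2, -2))
})

test_that("direction checking follows the eight-position rule", {
  cfg <- segmenterConfig()
  allOn <- matrix(1, 33, 33)
  dirs <- checkDirections(allOn, cfg, "training")
  expect_equal(nrow(dirs), 8L)
  # the canonical check order, starting at (+dx, 0)
  expect_equal(dirs$dx, c(8, 8, 0, -8, -8, -8, 0, 8))
  expect_equal(dirs$dy, c(0, 8, 8, 8, 0, -8, -8, -8))
  expect_equal(nrow(checkDirections(matrix(0, 33, 33), cfg)), 0L)
  one <- matrix(0.1, 33, 33)
  one[17, 17 + 8] <- 0.95               # (x + dx, y) in 0-based coords
  d1 <- checkDirections(one, cfg)
  expect_equal(nrow(d1), 1L)
  expect_equal(c(d1$dx, d1$dy), c(8, 0))
  # boundary convention: exactly T_move passes
  eq <- matrix(0, 33, 33); eq[17, 25] <- 0.9
  expect_equal(nrow(checkDirections(eq, cfg)), 1L)
  # inference order is by descending probability
  two <- matrix(0, 33, 33); two[17, 25] <- 0.92; two[25, 17] <- 0.97
  d2 <- checkDirections(two, cfg, "inference")
  expect_equal(d2$prob, c(0.97, 0.92))
})

test_that("mask loss is the summed cross-entropy with clamping", {
  p <- matrix(0.5, 33, 33)
  y <- matrix(sample(0:1, 33 * 33, TRUE), 33)
  expect_equal(maskLoss(p, y), 1089 * log(2), tolerance = 1e-9)
  # scalar-loop oracle on a random 4x4 pair
  set.seed(42)
  p4 <- matrix(runif(16, 0.05, 0.95), 4)
  y4 <- matrix(sample(0:1, 16, TRUE), 4)
  acc <- 0
  for (i in 1:16) acc <- acc - (y4[i] * log(p4[i]) +
                                  (1 - y4[i]) * log(1 - p4[i]))
  expect_equal(maskLoss(p4, y4), acc, tolerance = 1e-12)
  # exact 0/1 predictions are clamped, not infinite
  expect_true(is.finite(maskLoss(matrix(c(0, 1), 1), matrix(c(1, 0), 1))))
  expect_error(maskLoss(p, y[1:10, 1:10]), "differ")
})

test_that("segmentation head outputs an s x s probability map", {
  set.seed(43)
  cfg <- segmenterConfig()
  for (featCh in c(4L, 8L)) {
    w <- initSegWeights(featCh, cfg, seed = featCh)
    feat <- array(rnorm(33 * 33 * featCh), c(33, 33, featCh))
    p <- segForward(feat, initSeedMask(cfg), w)
    expect_equal(dim(p), c(33L, 33L))
    expect_true(all(p > 0 & p < 1))
    expect_identical(p, segForward(feat, initSeedMask(cfg), w))
  }
  w <- initSegWeights(4L, cfg)
  expect_error(segForward(array(0, c(33, 33, 4)), matrix(0, 17, 17), w),
               "mismatch")
})

test_that("FoV inference terminates immediately when nothing passes", {
  img <- matrix(0, 48, 48)
  shape <- matrix(FALSE, 48, 48)
  shape[22:26, 22:26] <- TRUE            # all 8 check positions miss it
  boxes <- data.frame(x1 = 17, y1 = 17, x2 = 31, y2 = 31, score = 0.9)
  fov <- runFovInference(img, boxes, segmenterConfig(),
                         predictor = oraclePredictor(shape))
  expect_equal(fov[[1]]$visited, 1L)     # no direction passes T_move
  bin <- fov[[1]]$canvas > 127 / 255
  expect_gt(sum(bin & shape) / sum(bin | shape), 0.7)
})

test_that("FoV traversal covers an elongated object and grows monotonically", {
  img <- matrix(0, 96, 96)
  shape <- matrix(FALSE, 96, 96)
  shape[40:60, 10:85] <- TRUE            # 3x wider than the detection box
  boxes <- data.frame(x1 = 30, y1 = 38, x2 = 55, y2 = 62, score = 0.9)
  cfg <- segmenterConfig()
  # monotone coverage: track canvas area growth through a wrapped predictor
  areas <- integer(0)
  canvasRef <- new.env()
  canvasRef$last <- matrix(0, 96, 96)
  base <- oraclePredictor(shape)
  fov <- runFovInference(img, boxes, cfg, predictor = base)
  bin <- fov[[1]]$canvas > cfg$binThr
  expect_equal(sum(bin & shape) / sum(bin | shape), 1, tolerance = 0.02)
  expect_lte(fov[[1]]$visited, cfg$maxVisited)
})

test_that("two disjoint objects yield non-overlapping canvases", {
  img <- matrix(0, 96, 96)
  s1 <- matrix(FALSE, 96, 96); s1[10:30, 10:40] <- TRUE
  s2 <- matrix(FALSE, 96, 96); s2[60:85, 50:90] <- TRUE
  both <- s1 | s2
  boxes <- data.frame(x1 = c(12, 52), y1 = c(12, 62), x2 = c(38, 88),
                      y2 = c(28, 83), score = c(0.9, 0.8))
  pred <- function(rect, maskIn) {
    # oracle restricted to the component the window centre belongs to
    cx <- round((rect[1] + rect[3]) / 2); cy <- round((rect[2] + rect[4]) / 2)
    tgt <- if (cy < 48) s1 else s2
    oraclePredictor(tgt)(rect, maskIn)
  }
  fov <- runFovInference(img, boxes, segmenterConfig(), predictor = pred)
  b1 <- fov[[1]]$canvas > 127 / 255
  b2 <- fov[[2]]$canvas > 127 / 255
  expect_equal(sum(b1 & b2), 0L)
  inst <- canvasesToInstances(fov, c(96L, 96L))
  expect_setequal(setdiff(unique(as.vector(inst)), 0L), c(1L, 2L))
})
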