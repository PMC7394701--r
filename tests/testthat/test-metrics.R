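test_that("binarization uses strict inequality at 127/255", {
  expect_false(any(binarizeProb(matrix(0, 4, 4))))
  expect_false(binarizeProb(matrix(127 / 255, 1, 1))[1])   # boundary -> bg
  expect_true(binarizeProb(matrix(128 / 255, 1, 1))[1])
  set.seed(1)
  p <- matrix(runif(400), 20)
  expect_identical(binarizeProb(p), p > 127 / 255)
})

test_that("confusion counts match a per-pixel loop oracle", {
  t10 <- c(rep(TRUE, 6), rep(FALSE, 4))
  expect_equal(confusionCounts(t10, t10),
               list(TP = 6L, FP = 0L, FN = 0L, TN = 4L))
  c2 <- confusionCounts(!t10, t10)
  expect_equal(c2$TP, 0L); expect_equal(c2$TN, 0L)
  set.seed(4)
  pred <- matrix(runif(64 * 64) > 0.5, 64)
  truth <- matrix(runif(64 * 64) > 0.7, 64)
  cc <- confusionCounts(pred, truth)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i]) fp <- fp + 1L
    else if (truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_equal(cc, list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_error(confusionCounts(pred, truth[1:10, 1:10]), "differ")
})

test_that("metric report reproduces the standard formulas", {
  r <- metricReport(list(TP = 6, FP = 2, FN = 2, TN = 90))
  expect_equal(r$jaccard, 0.6)
  expect_equal(r$dice, 0.75)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$accuracy, 0.96)
  expect_equal(r$fscore, 0.75)
  perfect <- metricReport(list(TP = 10, FP = 0, FN = 0, TN = 90))
  for (m in c("jaccard", "accuracy", "precision", "recall", "dice", "fscore"))
    expect_equal(perfect[[m]], 1)
  empty <- metricReport(list(TP = 0, FP = 0, FN = 5, TN = 95))
  expect_equal(empty$jaccard, 0)
  expect_equal(empty$recall, 0)
  expect_equal(empty$dice, 0)
  expect_true("precision" %in% empty$undefined)
})

test_that("jaccard <= dice and dice = 2J/(1+J) over random counts", {
  set.seed(5)
  for (i in 1:200) {
    cc <- as.list(sample(0:50, 4, TRUE))
    names(cc) <- c("TP", "FP", "FN", "TN")
    if (sum(unlist(cc)) == 0) next
    r <- metricReport(cc)
    expect_gte(r$dice, r$jaccard)
    expect_lte(r$dice, 1); expect_gte(r$jaccard, 0)
    if (cc$TP + cc$FP + cc$FN > 0)
      expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
  }
})
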