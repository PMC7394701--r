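test_that("class prediction is argmax with lowest-index tie-breaking", {
  s <- array(0, c(1, 1, 3)); s[1, 1, ] <- c(0.1, 0.7, 0.2)
  expect_equal(predictClasses(s)[1, 1], 1L)
  u <- array(0.3, c(2, 2, 3))
  expect_true(all(predictClasses(u) == 0L))
  set.seed(51)
  sc <- array(rnorm(20 * 20 * 3), c(20, 20, 3))
  got <- predictClasses(sc)
  for (i in 1:20) for (j in 1:20)
    expect_equal(got[i, j], which.max(sc[i, j, ]) - 1L)
})

test_that("relabeling separates membrane from ER by interior adjacency", {
  # an annulus around the interior plus a distant tubule
  cm <- matrix(0L, 40, 40)
  ym <- matrix(seq_len(40) - 12, 40, 40)
  xm <- matrix(seq_len(40) - 12, 40, 40, byrow = TRUE)
  dd <- ym^2 + xm^2
  interior <- dd <= 36
  annulus <- dd > 36 & dd <= 64
  cm[annulus] <- 1L                      # network called it ER
  cm[30:32, 25:38] <- 1L                 # a true ER tubule far away
  out <- relabelErNucMembrane(cm, interior)
  expect_true(all(out[annulus] == 2L))   # annulus -> nuclear membrane
  expect_true(all(out[30:32, 25:38] == 1L))
  # foreground partition unchanged
  expect_identical(out > 0L, cm > 0L)
  # idempotent
  expect_identical(relabelErNucMembrane(out, interior), out)
})

test_that("relabeling edge cases: no foreground, no adjacency, no interior", {
  cm <- matrix(0L, 10, 10)
  expect_identical(relabelErNucMembrane(cm, matrix(TRUE, 10, 10)), cm)
  scattered <- matrix(0L, 20, 20)
  scattered[2:3, 2:3] <- 2L; scattered[15:16, 15:17] <- 2L
  interior <- matrix(FALSE, 20, 20); interior[9:11, 9:11] <- TRUE
  out <- relabelErNucMembrane(scattered, interior)
  expect_true(all(out[scattered > 0L] == 1L))   # none adjacent -> all ER
  expect_warning(
    out2 <- relabelErNucMembrane(scattered, matrix(FALSE, 20, 20)),
    "interior")
  expect_true(all(out2[scattered > 0L] == 1L))
})

test_that("relabeling recovers the true split on oracle phantom class maps", {
  for (seed in c(2, 5, 11)) {
    ph <- tinyPhantom(seed, nz = 3L, side = 64L, nMito = 0L, nucleus = TRUE,
                      nEr = 2L, zspan = c(1L, 2L))
    tr <- ph$truth
    cm <- matrix(0L, 64, 64)
    cm[tr@er[1, , ]] <- 1L
    cm[tr@nucMembrane[1, , ]] <- 1L      # oracle semantic map: one class
    out <- relabelErNucMembrane(cm, tr@nucInterior[1, , ])
    expect_identical(out == 2L, tr@nucMembrane[1, , ])
    expect_identical(out == 1L, tr@er[1, , ])
  }
})

test_that("ER network output has the input's spatial size and 3 channels", {
  set.seed(52)
  w <- initErWeights(erNetConfig(ch = 4L), seed = 3)
  img <- matrix(runif(64 * 64), 64)
  s <- erForward(img, w)
  expect_equal(dim(s), c(64L, 64L, 3L))
  expect_identical(s, erForward(img, w))
  # non-multiple-of-32 side is padded internally and cropped back
  img2 <- matrix(runif(50 * 70), 50)
  expect_equal(dim(erForward(img2, w)), c(50L, 70L, 3L))
})
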