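test_that("phantoms are deterministic per seed and honour the config", {
  ph1 <- tinyPhantom(42)
  ph2 <- tinyPhantom(42)
  expect_identical(voxels(ph1$stack), voxels(ph2$stack))
  expect_identical(labels3d(ph1$truth@mito), labels3d(ph2$truth@mito))
  # requested counts and z-spans
  lab <- labels3d(ph1$truth@mito)
  ids <- idSet(ph1$truth@mito)
  expect_equal(length(ids), ph1$placedMito)
  for (id in ids) {
    span <- length(unique(which(lab == id, arr.ind = TRUE)[, 1]))
    expect_gte(span, 15L); expect_lte(span, 20L)
  }
})

test_that("empty phantom config produces pure background", {
  ph <- generatePhantom(phantomConfig(shape = c(4L, 32L, 32L), nMito = 0L,
                                      mitoZspanRange = c(1L, 2L),
                                      nErTubules = 0L, nucleus = FALSE,
                                      seed = 9))
  expect_equal(length(idSet(ph$truth@mito)), 0L)
  expect_false(any(ph$truth@er))
  expect_false(any(ph$truth@nucMembrane))
  expect_gt(sd(voxels(ph$stack)), 0)   # texture + noise present
})

test_that("truth classes are pairwise disjoint across seeds", {
  for (seed in 1:20) {
    ph <- tinyPhantom(seed, nz = 8L, side = 48L, nMito = 2L,
                      nucleus = TRUE, nEr = 2L, zspan = c(4L, 8L))
    expect_true(validObject(ph$truth))   # validity enforces disjointness
  }
})

test_that("foreground and background intensities are separable", {
  ph <- tinyPhantom(3)
  fg <- labels3d(ph$truth@mito) > 0L
  v <- voxels(ph$stack)
  # mitochondria are darker than the background on average
  expect_lt(mean(v[fg]), mean(v[!fg]) - 0.05)
  expect_lt(suppressWarnings(
    wilcox.test(sample(v[fg], 500), sample(v[!fg], 500))$p.value), 1e-6)
})

test_that("augmentation applies one geometric transform to both layers", {
  set.seed(21)
  img <- matrix(runif(32 * 32), 32)
  lab <- matrix(0L, 32, 32); lab[5:12, 20:28] <- 3L; lab[25:30, 2:6] <- 9L
  # identity transform with zero noise
  a0 <- augmentPair(img, lab, seed = 1, noiseSigma = 0, rotK = 0L,
                    flipH = FALSE, flipV = FALSE)
  expect_equal(a0$image, img)
  expect_identical(a0$labels, lab)
  # horizontal flip is an involution
  a1 <- augmentPair(img, lab, 1, 0, rotK = 0L, flipH = TRUE, flipV = FALSE)
  a2 <- augmentPair(a1$image, a1$labels, 1, 0, rotK = 0L, flipH = TRUE,
                    flipV = FALSE)
  expect_equal(a2$image, img)
  expect_identical(a2$labels, lab)
  # label ids conserved under random transforms + noise
  for (s in 1:5) {
    aa <- augmentPair(img, lab, s)
    expect_setequal(setdiff(unique(as.vector(aa$labels)), 0L), c(3L, 9L))
    expect_true(is.integer(aa$labels))
  }
})
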