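test_that("ImageStack and LabelVolume enforce their invariants", {
  v <- array(runif(4 * 8 * 8), c(4, 8, 8))
  st <- ImageStack(v)
  expect_equal(spacingNm(st), c(50, 3, 3))
  expect_error(new("ImageStack", voxels = array(2, c(2, 2, 2)),
                   spacingNm = c(50, 3, 3), origin = c(0L, 0L, 0L)),
               "intensities")
  expect_error(new("ImageStack", voxels = v, spacingNm = c(0, 3, 3),
                   origin = c(0L, 0L, 0L)), "positive")
  # 8-bit integers are rescaled
  st8 <- ImageStack(array(255L, c(2, 2, 2)))
  expect_equal(max(voxels(st8)), 1)
  lab <- array(0L, c(2, 4, 4)); lab[1, 1, 1] <- 4L
  lv <- LabelVolume(lab)
  expect_identical(idSet(lv), 4L)
  expect_error(LabelVolume(array(-1L, c(2, 2, 2))), "non-negative")
  expect_output(show(st), "ImageStack")
  expect_output(show(lv), "1 instances")
})

test_that("Organelle3D accessors and validity work", {
  reg <- function(z, n) list(slice = z, id = 1L,
                             pixels = cbind(rep(2L, n), seq_len(n)),
                             area = n, centroid = c(2, mean(seq_len(n))))
  o <- new("Organelle3D", id = 1L, regions = list(reg(0L, 3L), reg(1L, 4L)),
           spacingNm = c(50, 3, 3))
  expect_equal(zLength(o), 2L)
  expect_equal(voxelCount(o), 7L)
  expect_error(new("Organelle3D", id = 1L,
                   regions = list(reg(1L, 3L), reg(0L, 4L)),
                   spacingNm = c(50, 3, 3)), "ordered")
  expect_output(show(o), "Organelle3D")
})

test_that("PhantomTruth rejects overlapping classes", {
  d <- c(2L, 4L, 4L)
  mito <- array(0L, d); mito[1, 1, 1] <- 1L
  er <- array(FALSE, d); er[1, 1, 1] <- TRUE   # overlaps the mito voxel
  expect_error(new("PhantomTruth", mito = LabelVolume(mito), er = er,
                   nucMembrane = array(FALSE, d),
                   nucInterior = array(FALSE, d)), "disjoint")
})
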