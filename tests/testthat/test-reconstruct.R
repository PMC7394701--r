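test_that("a z-spanning cylinder links into one object of full length", {
  m <- cylinderMask(20L, 48L, 1L, 20L, 8)
  inst <- array(0L, dim(m)); inst[m] <- 1L
  objs <- linkSlices(inst)
  expect_length(objs, 1L)
  expect_equal(zLength(objs[[1]]), 20L)
  expect_equal(voxelCount(objs[[1]]), sum(m))
})

test_that("linking separates disjoint objects and ignores id permutations", {
  m1 <- cylinderMask(16L, 64L, 1L, 16L, 6, cy = 16, cx = 16)
  m2 <- cylinderMask(16L, 64L, 3L, 14L, 7, cy = 48, cx = 44)
  inst <- array(0L, dim(m1)); inst[m1] <- 5L; inst[m2] <- 9L
  objs <- linkSlices(inst)
  expect_length(objs, 2L)
  # permute instance ids per slice: partition must be identical
  instP <- inst
  for (z in seq_len(16)) {
    sl <- instP[z, , ]
    sl[sl == 5L] <- 99L; sl[sl == 9L] <- 1L; sl[sl == 99L] <- 3L
    instP[z, , ] <- sl
  }
  objsP <- linkSlices(instP)
  expect_length(objsP, 2L)
  vols <- sort(vapply(objs, voxelCount, 0L))
  volsP <- sort(vapply(objsP, voxelCount, 0L))
  expect_identical(vols, volsP)
  masks <- lapply(objs, objectMask, dims = dim(inst))
  masksP <- lapply(objsP, objectMask, dims = dim(inst))
  expect_true(all(sort(sapply(masks, sum)) == sort(sapply(masksP, sum))))
})

test_that("a one-slice gap is bridged by linking and filled by rectify", {
  m <- cylinderMask(18L, 48L, 1L, 18L, 8)
  inst <- array(0L, dim(m)); inst[m] <- 1L
  inst[9, , ] <- 0L                      # hole in the middle
  objs <- linkSlices(inst, gap = 1L)
  expect_length(objs, 1L)
  expect_equal(zLength(objs[[1]]), 17L)
  fixed <- rectifyObjects(objs, dim(m)[2:3])
  expect_equal(zLength(fixed[[1]]), 18L)  # hole filled
  # filled slice resembles its neighbours
  reg9 <- Filter(function(r) r$slice == 8L, fixed[[1]]@regions)[[1]]
  truth9 <- which(m[9, , ], arr.ind = TRUE) - 1L
  expect_gt(nrow(reg9$pixels) / nrow(truth9), 0.85)
  expect_lt(nrow(reg9$pixels) / nrow(truth9), 1.15)
})

test_that("rectify leaves clean objects unchanged and removes debris", {
  m <- cylinderMask(10L, 40L, 1L, 10L, 7)
  inst <- array(0L, dim(m)); inst[m] <- 1L
  objs <- linkSlices(inst)
  fixed <- rectifyObjects(objs, dim(m)[2:3])
  expect_equal(objectMask(fixed[[1]], dim(m)), m)   # bit-exact
  # salt-and-pepper debris on one region is removed by the opening
  instSp <- inst
  sl <- instSp[5, , ]
  set.seed(61)
  sl[cbind(sample(c(2:8, 32:39), 5), sample(2:39, 5))] <- 1L
  instSp[5, , ] <- sl
  objsSp <- linkSlices(instSp)
  fixedSp <- rectifyObjects(objsSp, dim(m)[2:3])
  expect_equal(objectMask(fixedSp[[1]], dim(m)), m)
})

test_that("the z-length filter keeps exactly the long objects", {
  mk <- function(z0, z1, cy) {
    cylinderMask(24L, 72L, z0, z1, 5, cy = cy, cx = 36)
  }
  inst <- array(0L, c(24L, 72L, 72L))
  inst[mk(1L, 20L, 12)] <- 1L            # length 20
  inst[mk(2L, 16L, 34)] <- 2L            # length 15
  inst[mk(5L, 18L, 58)] <- 3L            # length 14
  objs <- linkSlices(inst)
  expect_length(objs, 3L)
  kept <- filterByLength(objs, 15L)
  expect_length(kept, 2L)
  expect_setequal(vapply(kept, zLength, 0L), c(20L, 15L))
  # idempotent
  expect_equal(summarizeObjects(filterByLength(kept, 15L)),
               summarizeObjects(kept))
  expect_length(filterByLength(objs, 1L), 3L)
  expect_length(filterByLength(objs, 25L), 0L)
})
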