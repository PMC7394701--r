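sp <- c(50, 3, 3)

test_that("cylinder skeleton runs along the axis with true endpoints", {
  m <- cylinderMask(24L, 96L, 3L, 22L, 30)   # r = 90 nm, length 1000 nm
  sk <- skeletonize3d(m, sp)
  expect_gt(nrow(sk@points), 5L)
  # endpoints near the axis end faces (z 125 / 1075 nm, xy centre 144 nm)
  ends <- sk@points[c(1, nrow(sk@points)), ]
  for (r in 1:2) {
    expect_lt(abs(ends[r, 1] - c(1075, 125)[r]), 50)   # within one z-voxel
    expect_lt(sqrt(sum((ends[r, 2:3] - 144)^2)), 15)   # near the axis
  }
  # interior points hug the axis
  mid <- sk@points[sk@points[, 1] > 300 & sk@points[, 1] < 900, , drop = FALSE]
  expect_lt(max(abs(mid[, 2] - 144)), 12)
})

test_that("a sphere degenerates to a point skeleton", {
  m <- ballMask(c(16L, 220L, 220L), c(400, 330, 330), 300, sp)
  sk <- skeletonize3d(m, sp)
  expect_equal(nrow(sk@points), 1L)
  expect_equal(sk@arcLengthNm, 0)
  expect_lt(sqrt(sum((sk@points[1, ] - c(400, 330, 330))^2)), 80)
})

test_that("the short branch of a Y is pruned from the main skeleton", {
  d <- c(30L, 160L, 64L)
  m <- array(FALSE, d)
  addBall <- function(zc, yc) {
    b <- ballMask(d, c(zc, yc, 96), 54, sp)
    m <<- m | b
  }
  for (zc in seq(100, 700, 25)) addBall(zc, 240)
  for (zc in seq(700, 1400, 25)) addBall(zc, 240 + (zc - 700) * 0.17)
  for (zc in seq(700, 850, 25)) addBall(zc, 240 - (zc - 700) * 0.4)
  sk <- skeletonize3d(m, sp)
  zr <- range(sk@points[, 1])
  expect_lt(zr[1], 220); expect_gt(zr[2], 1280)   # full trunk + long arm
  yEnd <- sk@points[which.max(sk@points[, 1]), 2]
  expect_gt(yEnd, 300)                            # ends on the long arm
})

test_that("polynomial smoothing is exact on lines and reduces to the mean", {
  t <- seq(0, 1, length.out = 12)
  line <- cbind(1000 * t, 50 + 100 * t, 200 - 80 * t)
  sk <- new("Skeleton", points = line, coeffs = list(),
            arcLengthNm = sum(sqrt(rowSums(diff(line)^2))))
  sm <- smoothSkeleton(sk, degree = 3)
  # resampled points stay on the line (residual ~ 0)
  dir <- c(1000, 100, -80) / sqrt(sum(c(1000, 100, -80)^2))
  for (i in seq_len(nrow(sm@points))) {
    v <- sm@points[i, ] - line[1, ]
    offAxis <- v - sum(v * dir) * dir
    expect_lt(sqrt(sum(offAxis^2)), 1e-6)
  }
  sm0 <- smoothSkeleton(sk, degree = 0)
  expect_true(all(abs(sweep(sm0@points, 2, colMeans(line))) < 1e-9))
  # noisy cubic matches the closed-form least-squares oracle
  set.seed(71)
  tt <- seq(0, 1, length.out = 40)
  y <- 5 + 3 * tt - 7 * tt^2 + 2 * tt^3 + rnorm(40, 0, 0.05)
  pts <- cbind(1000 * tt, y, y)
  skN <- new("Skeleton", points = pts, coeffs = list(), arcLengthNm = 1)
  smN <- smoothSkeleton(skN, degree = 3)
  # normal-equations oracle in the same normalised arc-length parameter
  seg <- sqrt(rowSums(diff(pts)^2))
  tArc <- c(0, cumsum(seg)); tArc <- tArc / tArc[length(tArc)]
  X <- outer(tArc, 0:3, "^")
  co <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(as.numeric(smN@coeffs[[2]]), as.numeric(co), tolerance = 1e-6)
  expect_warning(smoothSkeleton(new("Skeleton",
                                    points = pts[1:3, ], coeffs = list(),
                                    arcLengthNm = 1), degree = 3), "degree")
})

test_that("cylinder cross sections match the analytic circle", {
  m <- cylinderMask(24L, 128L, 3L, 22L, 50)   # r = 150 nm
  sk <- smoothSkeleton(skeletonize3d(m, sp))
  cs <- crossSections(m, sk, nPoints = 10, sp)
  mid <- cs[!cs$skipped & cs$t > 0.3 & cs$t < 0.7, ]
  expect_gt(nrow(mid), 2L)
  expect_lt(abs(mean(mid$areaUm2) / (pi * 0.15^2) - 1), 0.05)
  expect_lt(abs(mean(mid$perimeterUm) / (2 * pi * 0.15) - 1), 0.05)
  # a different raster extent (hence step) changes the area by < 2%
  cs2 <- crossSections(m, sk, nPoints = 10, sp, maxHalfExtentNm = 300)
  mid2 <- cs2[!cs2$skipped & cs2$t > 0.3 & cs2$t < 0.7, ]
  expect_lt(abs(mean(mid2$areaUm2) / mean(mid$areaUm2) - 1), 0.02)
})

test_that("planes beyond the object are skipped with a flag", {
  m <- cylinderMask(24L, 64L, 8L, 16L, 10)
  sk <- smoothSkeleton(skeletonize3d(m, sp))
  # extrapolate an anchor far outside by forging coefficients
  skFar <- new("Skeleton", points = sk@points,
               coeffs = list(c(5000, 0), c(96, 0), c(96, 0)),
               arcLengthNm = sk@arcLengthNm)
  cs <- crossSections(m, skFar, nPoints = 3, sp)
  expect_true(all(cs$skipped))
})

test_that("volume and surface match analytic solids", {
  # exact voxel-count volume on a box
  box <- array(FALSE, c(4L, 12L, 12L))
  box[2:3, 2:11, 2:11] <- TRUE
  vs <- volumeSurface(box, c(50, 3, 3))
  expect_equal(vs$volumeUm3, 200 * 3 * 3 * 50 * 1e-9, tolerance = 1e-12)
  # digitized sphere r = 300 nm
  m <- ballMask(c(16L, 220L, 220L), c(400, 330, 330), 300, sp)
  vs2 <- volumeSurface(m, sp)
  expect_lt(abs(vs2$volumeUm3 / (4 / 3 * pi * 0.3^3) - 1), 0.05)
  expect_lt(abs(vs2$surfaceUm2 / (4 * pi * 0.3^2) - 1), 0.10)
  # face counting overestimates a sphere's surface; still same order
  vsF <- volumeSurface(m, sp, method = "faces")
  expect_gt(vsF$surfaceUm2, vs2$surfaceUm2 * 0.9)
  expect_warning(ve <- volumeSurface(array(FALSE, c(2, 2, 2)), sp), "empty")
  expect_equal(ve$volumeUm3, 0); expect_equal(ve$surfaceUm2, 0)
})

test_that("minimum distances honour exact geometry and contact rules", {
  d <- c(8L, 40L, 60L)
  # single-voxel objects 10 x-voxels apart: exactly 30 nm at 3 nm spacing
  sv1 <- array(FALSE, d); sv1[4, 20, 10] <- TRUE
  sv2 <- array(FALSE, d); sv2[4, 20, 20] <- TRUE
  expect_equal(minDistance(sv1, sv2, sp)$minDistanceNm, 30,
               tolerance = 1e-9)
  a <- array(FALSE, d); a[3:6, 10:20, 10:20] <- TRUE
  b <- array(FALSE, d); b[3:6, 10:20, 31:40] <- TRUE
  r <- minDistance(a, b, sp)
  # exact face gap is 33 nm centre-to-centre; estimate bounded above by
  # one coarse-cell diagonal
  expect_gte(r$minDistanceNm, 33 - 1e-9)
  expect_lte(r$minDistanceNm, 33 + sqrt(sum((c(2, 4, 4) * sp)^2)) + 1e-9)
  expect_false(r$isDirectContact)
  expect_equal(r$band, ">=30nm")
  # symmetric
  r2 <- minDistance(b, a, sp)
  expect_equal(r2$minDistanceNm, r$minDistanceNm)
  # touching boxes: direct contact, distance 0
  bt <- array(FALSE, d); bt[3:6, 10:20, 21:30] <- TRUE
  rt <- minDistance(a, bt, sp)
  expect_true(rt$isDirectContact)
  expect_equal(rt$minDistanceNm, 0)
  expect_equal(rt$band, "direct")
  # under-30 band
  bu <- array(FALSE, d); bu[3:6, 10:20, 26:35] <- TRUE
  expect_equal(minDistance(a, bu, sp)$band, "<30nm")
  expect_error(minDistance(array(FALSE, d), b, sp), "mitoMask")
  expect_error(minDistance(a, array(FALSE, d), sp), "erMask")
})

test_that("downsampled distances bound the exact value from above", {
  set.seed(72)
  for (i in 1:6) {
    d <- c(10L, 48L, 48L)
    a <- array(FALSE, d)
    b <- array(FALSE, d)
    az <- sort(sample(1:8, 2)); ay <- sort(sample(1:20, 2)); ax <- sort(sample(1:20, 2))
    a[az[1]:(az[2] + 1), ay[1]:(ay[2] + 4), ax[1]:(ax[2] + 4)] <- TRUE
    bz <- sort(sample(3:9, 2)); by <- sort(sample(26:42, 2)); bx <- sort(sample(26:42, 2))
    b[bz[1]:(bz[2] + 1), by[1]:(by[2] + 4), bx[1]:(bx[2] + 4)] <- TRUE
    est <- minDistance(a, b, sp)$minDistanceNm
    # full-resolution brute force over boundary voxels
    bnd <- function(m) {
      w <- which(m & !OrganelleEM:::.erode6(m), arr.ind = TRUE)
      sweep(w - 0.5, 2, sp, "*")
    }
    A <- bnd(a); B <- bnd(b)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exact <- sqrt(max(0, min(d2)))
    diag <- sqrt(sum((c(2, 4, 4) * sp)^2))
    expect_gte(est, exact - 1e-9)
    expect_lte(est, exact + diag + 1e-9)
  }
})

test_that("contact statistics tally the bands", {
  recs <- list(list(mitoId = 1L, minDistanceNm = 0, isDirectContact = TRUE,
                    band = "direct"),
               list(mitoId = 2L, minDistanceNm = 10, isDirectContact = FALSE,
                    band = "<30nm"),
               list(mitoId = 3L, minDistanceNm = 50, isDirectContact = FALSE,
                    band = ">=30nm"))
  cs <- contactStats(recs)
  expect_equal(cs$fracDirect, 1 / 3)
  expect_equal(cs$fracUnder30, 1 / 3)
  expect_equal(cs$frac30plus, 1 / 3)
  expect_equal(cs$fracDirect + cs$fracUnder30 + cs$frac30plus, 1)
  expect_equal(cs$meanDistanceNm, 20)
  allDirect <- recs[c(1, 1, 1)]
  expect_equal(contactStats(allDirect)$fracDirect, 1)
})
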