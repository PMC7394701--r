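# finite-difference gradient checks for the layer library; these guard the
# hand-derived backward passes that all three networks rely on

fdCheck <- function(lossFn, x, dx, eps = 1e-5, tol = 1e-3) {
  idx <- sample(length(x), min(5L, length(x)))
  for (i in idx) {
    x2 <- x; x2[i] <- x2[i] + eps
    num <- (lossFn(x2) - lossFn(x)) / eps
    expect_equal(dx[i], num, tolerance = tol)
  }
}

test_that("conv2d forward/backward agree with finite differences", {
  set.seed(11)
  x <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  p <- OrganelleEM:::nnConvInit(3, 2, 3)
  for (stride in c(1L, 2L)) {
    fwd <- OrganelleEM:::nnConvFwd(x, p, stride)
    bwd <- OrganelleEM:::nnConvBwd(2 * fwd$y, p, fwd$cache)
    lossX <- function(xx) sum(OrganelleEM:::nnConvFwd(xx, p, stride)$y^2)
    fdCheck(lossX, x, bwd$dx)
    lossW <- function(W) {
      p2 <- p; p2$W <- W
      sum(OrganelleEM:::nnConvFwd(x, p2, stride)$y^2)
    }
    fdCheck(lossW, p$W, bwd$dW)
  }
})

test_that("batch norm backward matches finite differences", {
  set.seed(12)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  p <- OrganelleEM:::nnBnInit(3)
  p$gamma <- runif(3, 0.5, 1.5); p$beta <- rnorm(3)
  fwd <- OrganelleEM:::nnBnFwd(x, p)
  bwd <- OrganelleEM:::nnBnBwd(2 * fwd$y, p, fwd$cache)
  fdCheck(function(xx) sum(OrganelleEM:::nnBnFwd(xx, p)$y^2), x, bwd$dx,
          tol = 5e-3)
  fdCheck(function(g) {
    p2 <- p; p2$gamma <- g
    sum(OrganelleEM:::nnBnFwd(x, p2)$y^2)
  }, p$gamma, bwd$dgamma, tol = 5e-3)
})

test_that("residual unit backward matches finite differences", {
  set.seed(13)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  p <- OrganelleEM:::resInit(4)
  fwd <- OrganelleEM:::resFwd(x, p)
  bwd <- OrganelleEM:::resBwd(2 * fwd$y, p, fwd$cache)
  fdCheck(function(xx) sum(OrganelleEM:::resFwd(xx, p)$y^2), x, bwd$dx,
          tol = 5e-3)
})

test_that("upsample/subsample are exact adjoints", {
  set.seed(14)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  up <- OrganelleEM:::nnUp2Fwd(x)
  expect_equal(dim(up), c(8L, 12L, 2L))
  expect_equal(up[1, 1, ], x[1, 1, ]); expect_equal(up[2, 2, ], x[1, 1, ])
  dy <- array(rnorm(length(up)), dim(up))
  # adjoint identity <up(x), dy> = <x, upBwd(dy)>
  expect_equal(sum(up * dy), sum(x * OrganelleEM:::nnUp2Bwd(dy)),
               tolerance = 1e-10)
  sub <- OrganelleEM:::nnSub2Fwd(x)
  dys <- array(rnorm(length(sub)), dim(sub))
  expect_equal(sum(sub * dys),
               sum(x * OrganelleEM:::nnSub2Bwd(dys, dim(x))),
               tolerance = 1e-10)
})

test_that("softmax cross-entropy and smooth-L1 losses and grads are correct", {
  set.seed(15)
  lg <- matrix(rnorm(8), 4, 2)
  t <- c(1L, 2L, 2L, 1L)
  ce <- OrganelleEM:::nnSoftmaxCE(lg, t)
  p <- exp(lg) / rowSums(exp(lg))
  expect_equal(ce$loss, -mean(log(p[cbind(1:4, t)])), tolerance = 1e-12)
  eps <- 1e-6
  lg2 <- lg; lg2[2, 1] <- lg2[2, 1] + eps
  expect_equal(ce$dlogits[2, 1],
               (OrganelleEM:::nnSoftmaxCE(lg2, t)$loss - ce$loss) / eps,
               tolerance = 1e-4)
  x <- matrix(c(-2, -0.5, 0.3, 1.7), 1)
  t2 <- matrix(0, 1, 4)
  sl <- OrganelleEM:::nnSmoothL1(x, t2)
  expect_equal(sl$loss, (2 - 0.5) + 0.5 * 0.25 + 0.5 * 0.09 + (1.7 - 0.5),
               tolerance = 1e-12)
})
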