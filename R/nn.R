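# Minimal convolutional network layer library with hand-derived backward
# passes.  Tensors are H x W x C arrays (batch of one); convolutions use
# im2col with cached index maps; normalization uses per-channel spatial
# statistics (batch-of-one batch norm).  Gradient correctness is checked by
# finite differences in the test suite.

.im2colCache <- new.env(parent = emptyenv())

.im2colIndex <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  got <- .im2colCache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  ho <- (Hp - k) %/% stride + 1L
  wo <- (Wp - k) %/% stride + 1L
  r0 <- rep((seq_len(ho) - 1L) * stride + 1L, times = wo)
  c0 <- rep((seq_len(wo) - 1L) * stride + 1L, each = ho)
  base <- r0 + (c0 - 1L) * Hp
  dr <- rep(0:(k - 1L), times = k * C)
  dc <- rep(rep(0:(k - 1L), each = k), times = C)
  ch <- rep(0:(C - 1L), each = k * k)
  offs <- dr + dc * Hp + ch * Hp * Wp
  I <- outer(base, offs, "+")
  out <- list(I = I, ho = ho, wo = wo, Hp = Hp, Wp = Wp)
  .im2colCache[[key]] <- out
  out
}

.pad2d <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  xp
}

#' @keywords internal
nnConvInit <- function(k, cin, cout, rng = NULL) {
  W <- matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(W = W, b = numeric(cout), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

#' @keywords internal
nnConvFwd <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  d <- dim(x)
  ix <- .im2colIndex(d[1], d[2], d[3], p$k, stride, pad)
  xp <- .pad2d(x, pad)
  cols <- matrix(xp[ix$I], nrow(ix$I), ncol(ix$I))
  y <- cols %*% p$W
  y <- sweep(y, 2, p$b, "+")
  list(y = array(y, c(ix$ho, ix$wo, p$cout)),
       cache = list(cols = cols, ix = ix, d = d, stride = stride, pad = pad))
}

#' @keywords internal
nnConvBwd <- function(dy, p, cache) {
  ix <- cache$ix
  dyM <- matrix(dy, ix$ho * ix$wo, p$cout)
  dW <- crossprod(cache$cols, dyM)
  db <- colSums(dyM)
  dcols <- dyM %*% t(p$W)
  dxp <- numeric(ix$Hp * ix$Wp * cache$d[3])
  I <- ix$I
  for (j in seq_len(ncol(I))) {
    idx <- I[, j]
    dxp[idx] <- dxp[idx] + dcols[, j]
  }
  dxp <- array(dxp, c(ix$Hp, ix$Wp, cache$d[3]))
  pad <- cache$pad
  dx <- if (pad > 0L)
    dxp[(pad + 1L):(pad + cache$d[1]), (pad + 1L):(pad + cache$d[2]), ,
        drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

#' @keywords internal
nnBnInit <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                             rm = numeric(c), rv = rep(1, c))

#' @keywords internal
nnBnFwd <- function(x, p, eps = 1e-5, training = TRUE) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (!training && !is.null(p$rm)) {
    istd <- 1 / sqrt(p$rv + eps)
    xhat <- sweep(sweep(xm, 2, p$rm), 2, istd, "*")
    y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    return(list(y = array(y, d), cache = NULL))
  }
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(y = array(y, d),
       cache = list(xhat = xhat, istd = istd, d = d, n = n, mu = mu, v = v))
}

#' @keywords internal
nnBnBwd <- function(dy, p, cache) {
  d <- cache$d; n <- cache$n
  dyM <- matrix(dy, n, d[3])
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  dxhat <- sweep(dyM, 2, p$gamma, "*")
  # dx = (istd/n) * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(n * dxhat, 2, s1) - sweep(cache$xhat, 2, s2, "*")
  dx <- sweep(dx, 2, cache$istd / n, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

#' @keywords internal
nnReluFwd <- function(x) list(y = pmax(x, 0), cache = x > 0)

#' @keywords internal
nnReluBwd <- function(dy, cache) dy * cache

#' @keywords internal
nnSigmoid <- function(z) 1 / (1 + exp(-z))

#' @keywords internal
nnUp2Fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

#' @keywords internal
nnUp2Bwd <- function(dy) {
  d <- dim(dy)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  dy[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
    dy[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
    dy[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE] +
    dy[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE]
}

# crop or zero-pad spatially to a target (h, w); used when merging pyramid
# levels whose sizes come from ceiling divisions
.fitTo <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  out <- array(0, c(h, w, d[3]))
  hh <- min(h, d[1]); ww <- min(w, d[2])
  out[seq_len(hh), seq_len(ww), ] <- x[seq_len(hh), seq_len(ww), , drop = FALSE]
  out
}

#' @keywords internal
nnSub2Fwd <- function(x) {
  d <- dim(x)
  x[seq(1L, d[1], 2L), seq(1L, d[2], 2L), , drop = FALSE]
}

#' @keywords internal
nnSub2Bwd <- function(dy, dIn) {
  dx <- array(0, dIn)
  dx[seq(1L, dIn[1], 2L), seq(1L, dIn[2], 2L), ] <- dy
  dx
}

#' @keywords internal
nnFcInit <- function(nin, nout) {
  list(W = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

#' @keywords internal
nnFcFwd <- function(x, p) {
  xm <- if (is.matrix(x)) x else matrix(x, 1L)
  list(y = sweep(xm %*% p$W, 2, p$b, "+"), cache = xm)
}

#' @keywords internal
nnFcBwd <- function(dy, p, cache) {
  list(dx = dy %*% t(p$W), dW = crossprod(cache, dy), db = colSums(dy))
}

# ---- composite conv-bn-relu block -----------------------------------------

#' @keywords internal
blockInit <- function(k, cin, cout)
  list(conv = nnConvInit(k, cin, cout), bn = nnBnInit(cout))

#' @keywords internal
blockFwd <- function(x, p, stride = 1L, training = TRUE) {
  c1 <- nnConvFwd(x, p$conv, stride = stride)
  b1 <- nnBnFwd(c1$y, p$bn, training = training)
  r1 <- nnReluFwd(b1$y)
  list(y = r1$y, cache = list(c = c1$cache, b = b1$cache, r = r1$cache))
}

#' @keywords internal
blockBwd <- function(dy, p, cache) {
  dr <- nnReluBwd(dy, cache$r)
  bb <- nnBnBwd(dr, p$bn, cache$b)
  cb <- nnConvBwd(bb$dx, p$conv, cache$c)
  list(dx = cb$dx,
       g = list(conv = list(W = cb$dW, b = cb$db),
                bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

# residual unit: two 3x3 conv-bn with identity skip, relu after the add
#' @keywords internal
resInit <- function(c)
  list(c1 = nnConvInit(3L, c, c), b1 = nnBnInit(c),
       c2 = nnConvInit(3L, c, c), b2 = nnBnInit(c))

#' @keywords internal
resFwd <- function(x, p) {
  a <- nnConvFwd(x, p$c1); ab <- nnBnFwd(a$y, p$b1); ar <- nnReluFwd(ab$y)
  b <- nnConvFwd(ar$y, p$c2); bb <- nnBnFwd(b$y, p$b2)
  s <- bb$y + x
  r <- nnReluFwd(s)
  list(y = r$y, cache = list(a = a$cache, ab = ab$cache, ar = ar$cache,
                             b = b$cache, bb = bb$cache, r = r$cache))
}

#' @keywords internal
resBwd <- function(dy, p, cache) {
  ds <- nnReluBwd(dy, cache$r)
  bbb <- nnBnBwd(ds, p$b2, cache$bb)
  bcb <- nnConvBwd(bbb$dx, p$c2, cache$b)
  dar <- nnReluBwd(bcb$dx, cache$ar)
  abb <- nnBnBwd(dar, p$b1, cache$ab)
  acb <- nnConvBwd(abb$dx, p$c1, cache$a)
  list(dx = acb$dx + ds,
       g = list(c1 = list(W = acb$dW, b = acb$db),
                b1 = list(gamma = abb$dgamma, beta = abb$dbeta),
                c2 = list(W = bcb$dW, b = bcb$db),
                b2 = list(gamma = bbb$dgamma, beta = bbb$dbeta)))
}

# ---- losses ---------------------------------------------------------------

#' Summed pixelwise binary cross-entropy (the segmentation mask loss)
#'
#' `sum_i -[y_i log p_i + (1 - y_i) log(1 - p_i)]`, summed (not averaged)
#' over pixels.  Predictions at exactly 0 or 1 are clamped at 1e-7.
#'
#' @param pred probability grid in (0, 1).
#' @param truth binary grid, same shape.
#' @return non-negative scalar.
#' @export
maskLoss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth shapes differ")
  eps <- 1e-7
  p <- .clamp(pred, eps, 1 - eps)
  y <- as.numeric(truth)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# 2-class softmax cross-entropy over rows of a logit matrix; targets in {1,2}
#' @keywords internal
nnSoftmaxCE <- function(logits, targets, reduce = "mean") {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), targets)
  li <- -log(pmax(p[idx], 1e-12))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  if (reduce == "mean") {
    list(loss = mean(li), dlogits = dlogits / n, p = p)
  } else list(loss = sum(li), dlogits = dlogits, p = p)
}

# smooth-L1 (Huber, delta = 1) summed over elements, averaged over rows
#' @keywords internal
nnSmoothL1 <- function(x, t) {
  d <- x - t
  a <- abs(d)
  l <- ifelse(a < 1, 0.5 * d^2, a - 0.5)
  g <- ifelse(a < 1, d, sign(d))
  n <- max(1L, NROW(x))
  list(loss = sum(l) / n, dx = g / n)
}

# ---- SGD with momentum ----------------------------------------------------

.mapNested <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- .mapNested(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    out
  } else f(a, b)
}

#' @keywords internal
sgdInit <- function(weights) .mapNested(function(w, .) w * 0, weights, NULL)

# returns list(weights, state); weight decay on matrices only
#' @keywords internal
sgdStep <- function(weights, grads, state, lr, momentum = 0.9,
                    weightDecay = 1e-4) {
  walk <- function(w, g, s) {
    if (is.list(w)) {
      nw <- w; ns <- s
      keys <- if (!is.null(names(w))) names(w) else seq_along(w)
      for (k in keys) {
        gk <- tryCatch(g[[k]], error = function(e) NULL)
        if (is.null(gk)) next
        r <- walk(w[[k]], gk, s[[k]])
        nw[[k]] <- r$w; ns[[k]] <- r$s
      }
      return(list(w = nw, s = ns))
    }
    if (is.numeric(w) && length(w) == length(g) && !is.integer(w)) {
      wd <- if (is.matrix(w)) weightDecay else 0
      v <- momentum * s + g + wd * w
      list(w = w - lr * v, s = v)
    } else list(w = w, s = s)
  }
  r <- walk(weights, grads, state)
  list(weights = r$w, state = r$s)
}

# keep only numeric leaves of a weights list when accumulating grads
#' @keywords internal
zeroGrads <- function(weights) .mapNested(function(w, .) w * 0, weights, NULL)

# clip a nested grad list to a global L2 norm
#' @keywords internal
clipGrads <- function(g, maxNorm = 5) {
  s <- 0
  walk <- function(x) {
    for (e in x) if (is.list(e)) walk(e) else if (is.numeric(e))
      s <<- s + sum(e^2)
  }
  walk(g)
  nrm <- sqrt(s)
  if (!is.finite(nrm) || nrm <= maxNorm) return(g)
  .mapNested(function(x, .) x * (maxNorm / nrm), g, NULL)
}

#' @keywords internal
addGrads <- function(a, b) .mapNested(function(x, y)
  if (is.null(y)) x else x + y, a, b)
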