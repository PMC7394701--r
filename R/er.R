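# ER / nuclear-membrane semantic segmentation: a fully convolutional
# residual encoder-decoder over 6 resolution steps with additive skip
# merges, a 3-class head (background-or-interior, ER, nuclear membrane),
# and the connected-component relabeling that separates ER from the
# nuclear membrane by adjacency to the nucleus interior.

#' ER network configuration
#'
#' @param ch uniform channel width (tiny CPU variant by default).
#' @param lr,momentum SGD settings (lr 0.01, momentum 0.9).
#' @return an `ErNetConfig` list.
#' @export
erNetConfig <- function(ch = 8L, lr = 0.01, momentum = 0.9) {
  cfg <- list(ch = as.integer(ch), lr = lr, momentum = momentum,
              nClasses = 3L)
  class(cfg) <- "ErNetConfig"
  cfg
}

#' Initialise ER network weights
#' @param cfg an [erNetConfig()]. @param seed RNG seed.
#' @export
initErWeights <- function(cfg = erNetConfig(), seed = 1L) {
  set.seed(seed)
  ch <- cfg$ch
  list(
    e1 = blockInit(3L, 1L, ch),                      # stride 1
    e2 = blockInit(3L, ch, ch), r2 = resInit(ch),    # stride 2
    e3 = blockInit(3L, ch, ch), r3 = resInit(ch),    # stride 4
    e4 = blockInit(3L, ch, ch), r4 = resInit(ch),    # stride 8
    e5 = blockInit(3L, ch, ch), r5 = resInit(ch),    # stride 16
    e6 = blockInit(3L, ch, ch), r6 = resInit(ch),    # stride 32
    d5 = list(conv = nnConvInit(3L, ch, ch), bn = nnBnInit(ch)),
    d4 = list(conv = nnConvInit(3L, ch, ch), bn = nnBnInit(ch)),
    d3 = list(conv = nnConvInit(3L, ch, ch), bn = nnBnInit(ch)),
    d2 = list(conv = nnConvInit(3L, ch, ch), bn = nnBnInit(ch)),
    d1 = list(conv = nnConvInit(3L, ch, ch), bn = nnBnInit(ch)),
    head = nnConvInit(1L, ch, cfg$nClasses)
  )
}

# decoder step: upsample -> 3x3 conv -> BN, additive skip merge, ReLU
.decFwd <- function(x, skip, p) {
  u <- nnUp2Fwd(x)
  u <- .fitTo(u, dim(skip)[1], dim(skip)[2])
  c1 <- nnConvFwd(u, p$conv)
  b1 <- nnBnFwd(c1$y, p$bn)
  s <- b1$y + skip
  r <- nnReluFwd(s)
  list(y = r$y, cache = list(c = c1$cache, b = b1$cache, r = r$cache,
                             dUp = dim(u)))
}

.decBwd <- function(dy, p, cache, dXdim) {
  ds <- nnReluBwd(dy, cache$r)
  bb <- nnBnBwd(ds, p$bn, cache$b)
  cb <- nnConvBwd(bb$dx, p$conv, cache$c)
  du <- .fitTo(cb$dx, 2L * dXdim[1], 2L * dXdim[2])
  list(dx = nnUp2Bwd(du), dSkip = ds,
       g = list(conv = list(W = cb$dW, b = cb$db),
                bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

#' Forward pass of the ER network
#'
#' @param imagePatch 2D matrix in [0, 1]; sides are padded internally to a
#'   multiple of 32 and the output cropped back.
#' @param weights from [initErWeights()].
#' @param cacheBwd keep caches for a backward pass (requires sides already
#'   divisible by 32).
#' @return H x W x 3 score array (higher = more likely class).
#' @export
erForward <- function(imagePatch, weights, cacheBwd = FALSE) {
  h0 <- nrow(imagePatch); w0 <- ncol(imagePatch)
  H <- as.integer(ceiling(h0 / 32) * 32); W <- as.integer(ceiling(w0 / 32) * 32)
  img <- matrix(0, H, W); img[seq_len(h0), seq_len(w0)] <- imagePatch
  x <- array(img, c(H, W, 1L))
  e1 <- blockFwd(x, weights$e1, 1L)
  e2 <- blockFwd(e1$y, weights$e2, 2L); r2 <- resFwd(e2$y, weights$r2)
  e3 <- blockFwd(r2$y, weights$e3, 2L); r3 <- resFwd(e3$y, weights$r3)
  e4 <- blockFwd(r3$y, weights$e4, 2L); r4 <- resFwd(e4$y, weights$r4)
  e5 <- blockFwd(r4$y, weights$e5, 2L); r5 <- resFwd(e5$y, weights$r5)
  e6 <- blockFwd(r5$y, weights$e6, 2L); r6 <- resFwd(e6$y, weights$r6)
  d5 <- .decFwd(r6$y, r5$y, weights$d5)
  d4 <- .decFwd(d5$y, r4$y, weights$d4)
  d3 <- .decFwd(d4$y, r3$y, weights$d3)
  d2 <- .decFwd(d3$y, r2$y, weights$d2)
  d1 <- .decFwd(d2$y, e1$y, weights$d1)
  hd <- nnConvFwd(d1$y, weights$head, pad = 0L)
  out <- hd$y[seq_len(h0), seq_len(w0), , drop = FALSE]
  if (cacheBwd)
    attr(out, "cache") <- list(e1 = e1, e2 = e2, r2 = r2, e3 = e3, r3 = r3,
                               e4 = e4, r4 = r4, e5 = e5, r5 = r5, e6 = e6,
                               r6 = r6, d5 = d5, d4 = d4, d3 = d3, d2 = d2,
                               d1 = d1, hd = hd, H = H, W = W)
  out
}

# one SGD step with mean 3-class softmax cross-entropy
#' @keywords internal
erTrainStep <- function(image, classes, weights, state, cfg) {
  scores <- erForward(image, weights, cacheBwd = TRUE)
  cache <- attr(scores, "cache")
  H <- cache$H; W <- cache$W
  n <- length(classes)
  logits <- matrix(scores, n, 3L)
  ce <- nnSoftmaxCE(logits, as.integer(classes) + 1L)
  dHead <- array(0, c(H, W, 3L))
  dHead[seq_len(nrow(image)), seq_len(ncol(image)), ] <-
    array(ce$dlogits, c(nrow(image), ncol(image), 3L))
  hb <- nnConvBwd(dHead, weights$head, cache$hd$cache)
  g <- list(head = list(W = hb$dW, b = hb$db))
  dd1 <- .decBwd(hb$dx, weights$d1, cache$d1$cache, dim(cache$d2$y))
  g$d1 <- dd1$g
  dd2 <- .decBwd(dd1$dx, weights$d2, cache$d2$cache, dim(cache$d3$y))
  g$d2 <- dd2$g
  dd3 <- .decBwd(dd2$dx, weights$d3, cache$d3$cache, dim(cache$d4$y))
  g$d3 <- dd3$g
  dd4 <- .decBwd(dd3$dx, weights$d4, cache$d4$cache, dim(cache$d5$y))
  g$d4 <- dd4$g
  dd5 <- .decBwd(dd4$dx, weights$d5, cache$d5$cache, dim(cache$r6$y))
  g$d5 <- dd5$g
  br6 <- resBwd(dd5$dx, weights$r6, cache$r6$cache); g$r6 <- br6$g
  be6 <- blockBwd(br6$dx, weights$e6, cache$e6$cache); g$e6 <- be6$g
  br5 <- resBwd(be6$dx + dd5$dSkip, weights$r5, cache$r5$cache); g$r5 <- br5$g
  be5 <- blockBwd(br5$dx, weights$e5, cache$e5$cache); g$e5 <- be5$g
  br4 <- resBwd(be5$dx + dd4$dSkip, weights$r4, cache$r4$cache); g$r4 <- br4$g
  be4 <- blockBwd(br4$dx, weights$e4, cache$e4$cache); g$e4 <- be4$g
  br3 <- resBwd(be4$dx + dd3$dSkip, weights$r3, cache$r3$cache); g$r3 <- br3$g
  be3 <- blockBwd(br3$dx, weights$e3, cache$e3$cache); g$e3 <- be3$g
  br2 <- resBwd(be3$dx + dd2$dSkip, weights$r2, cache$r2$cache); g$r2 <- br2$g
  be2 <- blockBwd(br2$dx, weights$e2, cache$e2$cache); g$e2 <- be2$g
  be1 <- blockBwd(be2$dx + dd1$dSkip, weights$e1, cache$e1$cache)
  g$e1 <- be1$g
  up <- sgdStep(weights, g, state, cfg$lr, cfg$momentum, 1e-4)
  list(weights = up$weights, state = up$state, loss = ce$loss)
}

#' Train the ER network
#'
#' @param samples list of `list(image =, classes = integer matrix with
#'   values 0 (background/interior), 1 (ER), 2 (nuclear membrane))`.
#' @param cfg an [erNetConfig()]. @param steps SGD steps. @param seed seed.
#' @return list(weights, lossTrace).
#' @export
trainErNet <- function(samples, cfg = erNetConfig(), steps = 300L,
                       seed = 1L) {
  set.seed(seed)
  weights <- initErWeights(cfg, seed)
  state <- sgdInit(weights)
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    i <- if (length(samples) == 1L) 1L else sample(length(samples), 1L)
    r <- erTrainStep(samples[[i]]$image, samples[[i]]$classes,
                     weights, state, cfg)
    weights <- r$weights; state <- r$state
    trace[s] <- r$loss
  }
  list(weights = weights, lossTrace = trace)
}

#' Per-pixel class decision from 3-class scores
#'
#' Argmax per pixel; ties broken by the lowest class index.
#'
#' @param scores H x W x 3 array.
#' @return integer H x W matrix with values 0, 1, 2.
#' @export
predictClasses <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  cl <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(cl), d[1], d[2])
}

#' Separate ER from nuclear membrane by interior adjacency
#'
#' Connected components (8-connectivity) of the foreground (ER union
#' nuclear membrane) that are adjacent to the nucleus interior — sharing an
#' edge or a corner with an interior pixel — are relabeled nuclear
#' membrane; all remaining foreground components become ER.  The
#' foreground/background partition is never changed, and the operation is
#' idempotent.
#'
#' @param cm integer class matrix (0 background/interior, 1 ER, 2 nuclear
#'   membrane) from [predictClasses()].
#' @param interiorMask logical matrix marking the nucleus interior.  When
#'   `NULL`, the interior is taken from the prediction itself as the
#'   class-0 connected components fully enclosed in the image (touching no
#'   border).
#' @return relabeled class matrix.
#' @export
relabelErNucMembrane <- function(cm, interiorMask = NULL) {
  fg <- cm > 0L
  if (!any(fg)) return(cm)
  if (is.null(interiorMask)) {
    bgLab <- labelComponents2D(!fg)
    border <- unique(c(bgLab[1, ], bgLab[nrow(bgLab), ],
                       bgLab[, 1], bgLab[, ncol(bgLab)]))
    interiorMask <- bgLab > 0L & !(bgLab %in% setdiff(border, 0L))
    interiorMask <- matrix(interiorMask, nrow(cm), ncol(cm))
  }
  if (!any(interiorMask)) {
    warning("empty nucleus interior: all foreground labeled ER")
    out <- cm; out[fg] <- 1L
    return(out)
  }
  comp <- labelComponents2D(fg)
  grown <- EBImage::dilate(matrix(as.numeric(interiorMask), nrow(cm)),
                           matrix(1, 3, 3)) > 0
  touching <- unique(comp[grown & comp > 0L])
  out <- cm
  out[fg] <- 1L
  if (length(touching) > 0L) out[comp %in% touching] <- 2L
  out
}

#' Predict and relabel ER / nuclear membrane classes for a whole stack
#'
#' @param stack an [ImageStack-class].
#' @param weights trained ER weights.
#' @param interior optional (z, y, x) logical array of the true interior.
#' @return integer (z, y, x) class array (0/1/2) after relabeling.
#' @export
predictEr <- function(stack, weights, interior = NULL) {
  v <- voxels(stack); d <- dim(v)
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    cm <- predictClasses(erForward(v[z, , ], weights))
    im <- if (is.null(interior)) NULL else interior[z, , ]
    out[z, , ] <- relabelErNucMembrane(cm, im)
  }
  out
}
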