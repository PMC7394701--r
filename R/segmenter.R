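# Recursive segmentation subnetwork: seeded mask refinement over a movable
# 33 x 33 field of view (FoV).  The mask channel carries probabilities
# between iterations; the FoV moves in eight directions whenever the
# probability at a candidate centre reaches the moving threshold, with the
# step scaled by the current box size so larger objects take larger steps.

#' Segmenter configuration
#'
#' @param s mask side (33).
#' @param step (dx, dy) movement step in mask units.
#' @param tMove moving threshold in (0, 1); a candidate centre is queued
#'   when its predicted probability is >= tMove.
#' @param seedValue activation written at the seed centre.
#' @param ch head width (channels of the four 3 x 3 convolutions).
#' @param lr,momentum SGD settings for the head.
#' @param maxVisited hard cap on FoV positions per object.
#' @param binThr canvas binarization threshold (8-bit 127 on [0,1]).
#' @param roiMinLevel finest pyramid level for RoI feature extraction
#'   (matches the detector's `roiMinLevel`; 0 in the tiny configuration).
#' @param nIter forward passes per FoV window at inference; after the
#'   first pass the updated probability map is fed back as the mask
#'   channel (the recursive refinement within one window).
#' @return a `SegmenterConfig` list.
#' @export
segmenterConfig <- function(s = 33L, step = c(8, 8), tMove = 0.9,
                            seedValue = 0.95, ch = 8L, lr = 0.02,
                            momentum = 0.9, maxVisited = 512L,
                            binThr = 127 / 255, roiMinLevel = 0L,
                            nIter = 2L) {
  stopifnot(tMove > 0, tMove < 1, all(step < s / 2))
  cfg <- list(s = as.integer(s), step = step, tMove = tMove,
              seedValue = seedValue, ch = as.integer(ch), lr = lr,
              momentum = momentum, maxVisited = as.integer(maxVisited),
              binThr = binThr, roiMinLevel = as.integer(roiMinLevel),
              nIter = as.integer(nIter))
  class(cfg) <- "SegmenterConfig"
  cfg
}

#' Initial seed mask
#'
#' All zeros except the centre position, which receives the seed
#' activation, marking that the centre pixel belongs to the target.  For
#' even sides the centre is at (s/2, s/2) by the floor convention.
#'
#' @param cfg a [segmenterConfig()].
#' @return s x s matrix.
#' @export
initSeedMask <- function(cfg = segmenterConfig()) {
  m <- matrix(0, cfg$s, cfg$s)
  c0 <- cfg$s %/% 2L + 1L   # 0-based floor(s/2) -> 1-based
  m[c0, c0] <- cfg$seedValue
  m
}

#' Initialise segmentation-head weights
#' @param featCh channels of the RoI feature input.
#' @param cfg a [segmenterConfig()].
#' @param seed RNG seed.
#' @export
initSegWeights <- function(featCh, cfg = segmenterConfig(), seed = 1L) {
  set.seed(seed)
  list(b1 = blockInit(3L, featCh + 1L, cfg$ch),
       b2 = blockInit(3L, cfg$ch, cfg$ch),
       b3 = blockInit(3L, cfg$ch, cfg$ch),
       b4 = blockInit(3L, cfg$ch, cfg$ch),
       out = nnConvInit(1L, cfg$ch, 1L))
}

#' Forward pass of the segmentation head
#'
#' Concatenates the RoI features with the object-mask channel, applies four
#' 3 x 3 conv + BN + ReLU layers and a final 1 x 1 convolution, and returns
#' the sigmoid probability map that both scores the current FoV and seeds
#' the next iteration's mask channel.
#'
#' @param roiFeatures s x s x C array.
#' @param maskIn s x s matrix (probabilities).
#' @param weights from [initSegWeights()].
#' @param cacheBwd keep caches for a backward pass.
#' @return s x s probability matrix in (0, 1); with attribute "cache" when
#'   `cacheBwd`.
#' @export
segForward <- function(roiFeatures, maskIn, weights, cacheBwd = FALSE,
                       training = cacheBwd) {
  d <- dim(roiFeatures)
  if (!identical(d[1:2], dim(maskIn))) stop("feature/mask shape mismatch")
  x <- array(c(roiFeatures, maskIn), c(d[1], d[2], d[3] + 1L))
  f1 <- blockFwd(x, weights$b1, training = training)
  f2 <- blockFwd(f1$y, weights$b2, training = training)
  f3 <- blockFwd(f2$y, weights$b3, training = training)
  f4 <- blockFwd(f3$y, weights$b4, training = training)
  z <- nnConvFwd(f4$y, weights$out, pad = 0L)
  p <- nnSigmoid(z$y[, , 1L])
  if (cacheBwd)
    attr(p, "cache") <- list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, z = z,
                             dIn = dim(x))
  p
}

# one SGD step on (features, maskIn, truth); loss is the summed BCE
#' @keywords internal
segTrainStep <- function(roiFeatures, maskIn, truth, weights, state, cfg) {
  p <- segForward(roiFeatures, maskIn, weights, cacheBwd = TRUE)
  cache <- attr(p, "cache")
  # update batch-norm running statistics (used at inference)
  a <- 0.05
  for (nm in c("b1", "b2", "b3", "b4")) {
    bc <- cache[[sub("b", "f", nm)]]$cache$b
    weights[[nm]]$bn$rm <- (1 - a) * weights[[nm]]$bn$rm + a * bc$mu
    weights[[nm]]$bn$rv <- (1 - a) * weights[[nm]]$bn$rv + a * bc$v
  }
  loss <- maskLoss(p, truth)
  dz <- array(p - truth, c(cfg$s, cfg$s, 1L))   # d(summed BCE)/d logits
  ob <- nnConvBwd(dz, weights$out, cache$z$cache)
  g4 <- blockBwd(ob$dx, weights$b4, cache$f4$cache)
  g3 <- blockBwd(g4$dx, weights$b3, cache$f3$cache)
  g2 <- blockBwd(g3$dx, weights$b2, cache$f2$cache)
  g1 <- blockBwd(g2$dx, weights$b1, cache$f1$cache)
  grads <- list(b1 = g1$g, b2 = g2$g, b3 = g3$g, b4 = g4$g,
                out = list(W = ob$dW, b = ob$db))
  grads <- clipGrads(grads, 10)
  up <- sgdStep(weights, grads, state, cfg$lr, cfg$momentum, 0)
  list(weights = up$weights, state = up$state, loss = loss)
}

#' Check the eight movement directions
#'
#' Inspects the eight positions (x + dx, y), (x + dx, y + dy), (x, y + dy),
#' (x - dx, y + dy), (x - dx, y), (x - dx, y - dy), (x, y - dy),
#' (x + dx, y - dy) around the FoV centre and returns those whose predicted
#' probability is greater than or equal to the moving threshold — in that
#' listed order for training, or sorted by descending probability for
#' inference (the queue discipline).
#'
#' @param prob s x s probability map of the current FoV.
#' @param cfg a [segmenterConfig()].
#' @param order `"training"` or `"inference"`.
#' @return data.frame (dx, dy, prob) of passing offsets (mask units).
#' @export
checkDirections <- function(prob, cfg = segmenterConfig(),
                            order = c("inference", "training")) {
  order <- match.arg(order)
  s <- cfg$s; dx <- cfg$step[1]; dy <- cfg$step[2]
  c0 <- s %/% 2L            # 0-based centre
  offs <- rbind(c(dx, 0), c(dx, dy), c(0, dy), c(-dx, dy), c(-dx, 0),
                c(-dx, -dy), c(0, -dy), c(dx, -dy))
  px <- c0 + offs[, 1]; py <- c0 + offs[, 2]
  ok <- px >= 0 & px < s & py >= 0 & py < s
  pv <- rep(-Inf, 8L)
  pv[ok] <- prob[cbind(py[ok] + 1L, px[ok] + 1L)]
  pass <- which(pv >= cfg$tMove)
  out <- data.frame(dx = offs[pass, 1], dy = offs[pass, 2], prob = pv[pass])
  if (order == "inference" && nrow(out) > 1L)
    out <- out[order(out$prob, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scale the movement step to image pixels
#'
#' (dx', dy') = (dx * w / s, dy * h / s): larger boxes take larger steps.
#' The result may be fractional; it is rounded half away from zero when
#' applied in image coordinates.
#'
#' @param w,h current box width and height in px (> 0).
#' @param cfg a [segmenterConfig()].
#' @return numeric (dxPx, dyPx), unrounded.
#' @export
scaleStep <- function(w, h, cfg = segmenterConfig()) {
  if (w <= 0 || h <= 0) stop("box dimensions must be positive")
  c(cfg$step[1] * w / cfg$s, cfg$step[2] * h / cfg$s)
}

# round half away from zero
#' @keywords internal
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# resize helper on [y, x] matrices
.resizeYX <- function(m, ny, nx, nearest = FALSE) {
  out <- EBImage::resize(m, w = ny, h = nx,
                         filter = if (nearest) "none" else "bilinear")
  matrix(as.numeric(out), ny, nx)
}

#' Run recursive FoV inference for detected boxes on one slice
#'
#' For each box: seed at the box centre, then repeatedly pop the
#' highest-priority centre from the queue, predict the local 33 x 33 mask,
#' write it into the object's slice-coordinate canvas (pixelwise maximum on
#' overlap), and push the passing directions scaled by the box size.  The
#' FoV window keeps the detection box's size; the union of visited windows
#' is the object's effective extent.  Terminates when the queue is empty or
#' the visited cap is reached.
#'
#' @param sliceImage 2D matrix (used for bounds; features come from
#'   `pyramid`).
#' @param boxes data.frame from [predictBoxes()] (x1, y1, x2, y2, score).
#' @param cfg a [segmenterConfig()].
#' @param pyramid feature pyramid of the slice (needed unless `predictor`
#'   is given).
#' @param segWeights trained head weights (unless `predictor`).
#' @param predictor optional `function(windowRect, maskIn)` returning a
#'   33 x 33 probability map; used to inject an oracle predictor.
#'   `windowRect` is (x1, y1, x2, y2) in image px.
#' @param onIteration optional callback `function(canvas)` invoked after
#'   every canvas write (used by invariant tests).
#' @return list with one element per box:
#'   `list(canvas = prob matrix, visited = n, extent = union rect)`.
#' @export
runFovInference <- function(sliceImage, boxes, cfg = segmenterConfig(),
                            pyramid = NULL, segWeights = NULL,
                            predictor = NULL, onIteration = NULL) {
  imgH <- nrow(sliceImage); imgW <- ncol(sliceImage)
  if (is.null(predictor) && (is.null(pyramid) || is.null(segWeights)))
    stop("either a predictor or pyramid + segWeights must be supplied")
  netPredict <- function(rect, maskIn) {
    lv <- assignLevel(rect, minLevel = cfg$roiMinLevel)
    feat <- roiAlign(pyramid[[as.character(lv)]], rect, 2^lv,
                     outSize = cfg$s)
    p <- segForward(feat, maskIn, segWeights)
    for (it in seq_len(max(0L, cfg$nIter - 1L)))
      p <- segForward(feat, p, segWeights)   # feed back the updated map
    p
  }
  pred <- if (is.null(predictor)) netPredict else predictor
  out <- vector("list", nrow(boxes))
  for (bi in seq_len(nrow(boxes))) {
    bw <- max(boxes$x2[bi] - boxes$x1[bi], 4)
    bh <- max(boxes$y2[bi] - boxes$y1[bi], 4)
    cx <- (boxes$x1[bi] + boxes$x2[bi]) / 2
    cy <- (boxes$y1[bi] + boxes$y2[bi]) / 2
    stepPx <- roundHalfAway(scaleStep(bw, bh, cfg))
    stepPx <- pmax(stepPx, 1)
    canvas <- matrix(0, imgH, imgW)
    visited <- new.env(parent = emptyenv())
    queue <- data.frame(cx = round(cx), cy = round(cy), pri = 1)
    nVisited <- 0L
    extent <- c(Inf, Inf, -Inf, -Inf)
    first <- TRUE
    while (nrow(queue) > 0L) {
      if (nVisited >= cfg$maxVisited) {
        warning("FoV visited cap reached; object truncated")
        break
      }
      i <- which.max(queue$pri)
      ccx <- queue$cx[i]; ccy <- queue$cy[i]
      queue <- queue[-i, , drop = FALSE]
      key <- paste(ccx, ccy)
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      nVisited <- nVisited + 1L
      rect <- c(ccx - bw / 2, ccy - bh / 2, ccx + bw / 2, ccy + bh / 2)
      # pixel window, clipped to the image
      x0 <- max(0L, as.integer(floor(rect[1]))); y0 <- max(0L, as.integer(floor(rect[2])))
      x1 <- min(imgW, as.integer(ceiling(rect[3]))); y1 <- min(imgH, as.integer(ceiling(rect[4])))
      if (x1 - x0 < 2L || y1 - y0 < 2L) next
      winRect <- c(x0, y0, x1, y1)
      extent <- c(min(extent[1], x0), min(extent[2], y0),
                  max(extent[3], x1), max(extent[4], y1))
      maskIn <- if (first) initSeedMask(cfg) else
        .resizeYX(canvas[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
                  cfg$s, cfg$s)
      first <- FALSE
      prob <- pred(winRect, maskIn)
      # write back: resample to the window and max-merge
      probWin <- .resizeYX(prob, y1 - y0, x1 - x0)
      sub <- canvas[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
      canvas[(y0 + 1L):y1, (x0 + 1L):x1] <- pmax(sub, probWin)
      if (!is.null(onIteration)) onIteration(canvas)
      dirs <- checkDirections(prob, cfg, "inference")
      if (nrow(dirs) > 0L) for (k in seq_len(nrow(dirs))) {
        nx <- ccx + sign(dirs$dx[k]) * abs(stepPx[1]) *
          (abs(dirs$dx[k]) > 0)
        ny <- ccy + sign(dirs$dy[k]) * abs(stepPx[2]) *
          (abs(dirs$dy[k]) > 0)
        if (nx < 0 || nx >= imgW || ny < 0 || ny >= imgH) next
        k2 <- paste(nx, ny)
        if (is.null(visited[[k2]]))
          queue <- rbind(queue, data.frame(cx = nx, cy = ny,
                                           pri = dirs$prob[k]))
      }
    }
    out[[bi]] <- list(canvas = canvas, visited = nVisited,
                      extent = extent, score = boxes$score[bi])
  }
  out
}

#' Merge per-object canvases into one instance label map
#'
#' Canvases are binarized at the 127/255 threshold; where binarized
#' instances overlap, the instance whose detection score is higher wins.
#'
#' @param fovResults list from [runFovInference()].
#' @param imgShape (H, W).
#' @param cfg a [segmenterConfig()].
#' @return integer H x W instance map (0 background).
#' @export
canvasesToInstances <- function(fovResults, imgShape,
                                cfg = segmenterConfig()) {
  lab <- matrix(0L, imgShape[1], imgShape[2])
  scores <- vapply(fovResults, function(r) r$score, 0)
  claim <- matrix(-Inf, imgShape[1], imgShape[2])
  for (i in order(scores)) {   # ascending: higher scores overwrite later
    fg <- fovResults[[i]]$canvas > cfg$binThr
    take <- fg & scores[i] > claim
    lab[take] <- i
    claim[take] <- scores[i]
  }
  lab
}

#' Train the segmentation head on phantom instances
#'
#' Ground-truth boxes are jittered by up to 25% in shift and scale to
#' simulate detection results; RoI features come from the (frozen) detector
#' pyramid; the ground-truth local mask is resized with nearest-neighbour
#' interpolation to stay binary, the input mask channel bilinearly.  Half
#' of the steps feed the previous prediction back as the mask channel.
#'
#' @param slices list of `list(image =, instances = integer matrix)`.
#' @param detWeights trained detector weights (feature provider).
#' @param cfg a [segmenterConfig()].
#' @param steps SGD steps. @param seed RNG seed.
#' @param featCh pyramid channel count.
#' @return list(weights, lossTrace).
#' @export
trainMitoSegmenter <- function(slices, detWeights, cfg = segmenterConfig(),
                               steps = 400L, seed = 1L, featCh = 8L) {
  set.seed(seed)
  weights <- initSegWeights(featCh, cfg, seed)
  state <- sgdInit(weights)
  pyramids <- lapply(slices, function(s) buildPyramid(s$image, detWeights))
  # instance inventory
  inv <- list()
  for (si in seq_along(slices)) {
    ids <- setdiff(unique(as.vector(slices[[si]]$instances)), 0L)
    for (id in ids) inv[[length(inv) + 1L]] <- c(si, id)
  }
  if (length(inv) == 0L) stop("no instances to train on")
  trace <- numeric(steps)
  cropTo33 <- function(m, b, nearest) {
    x0 <- as.integer(floor(b[1])); y0 <- as.integer(floor(b[2]))
    x1 <- as.integer(ceiling(b[3])); y1 <- as.integer(ceiling(b[4]))
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, y1 - y0, x1 - x0)
    ys <- max(y0, 0L):(min(y1, H) - 1L); xs <- max(x0, 0L):(min(x1, W) - 1L)
    out[ys - y0 + 1L, xs - x0 + 1L] <- m[ys + 1L, xs + 1L]
    .resizeYX(out, cfg$s, cfg$s, nearest = nearest)
  }
  for (st in seq_len(steps)) {
    pick <- inv[[sample(length(inv), 1L)]]
    ins <- slices[[pick[1]]]$instances
    m <- (ins == pick[2]) * 1
    ys <- range(which(rowSums(m) > 0)); xs <- range(which(colSums(m) > 0))
    gt <- c(xs[1] - 1, ys[1] - 1, xs[2], ys[2])   # 0-based half-open
    # a fifth of the steps train on a background-only window of the same
    # box scale with an all-zero target: a spurious or overshot FoV must
    # predict empty, otherwise traversal floods the background
    mode <- {
      u <- runif(1)
      if (u < 0.15) "background" else if (u < 0.55) "moved"
      else if (u < 0.75) "feedback" else "seed"
    }
    if (mode == "background") {
      bw <- gt[3] - gt[1]; bh <- gt[4] - gt[2]
      placed <- FALSE
      for (try in 1:10) {
        x0 <- runif(1, 0, ncol(ins) - bw); y0 <- runif(1, 0, nrow(ins) - bh)
        bb <- c(x0, y0, x0 + bw, y0 + bh)
        crop <- ins[(floor(y0) + 1):ceiling(y0 + bh),
                    (floor(x0) + 1):ceiling(x0 + bw), drop = FALSE]
        if (all(crop == 0L)) { placed <- TRUE; break }
      }
      if (placed) {
        lv <- assignLevel(bb, minLevel = cfg$roiMinLevel)
        feat <- roiAlign(pyramids[[pick[1]]][[as.character(lv)]], bb, 2^lv,
                         outSize = cfg$s)
        maskIn <- if (runif(1) < 0.5) initSeedMask(cfg) else
          matrix(0, cfg$s, cfg$s)          # spurious / already-empty state
        cfgStep <- cfg
        if (st > 2L * steps %/% 3L) cfgStep$lr <- cfg$lr / 10
        r <- segTrainStep(feat, maskIn, matrix(0, cfg$s, cfg$s), weights,
                          state, cfgStep)
        weights <- r$weights; state <- r$state
        trace[st] <- r$loss
      }
      next
    }
    b <- jitterBox(gt)
    b <- clipBoxes(matrix(b, 1L), dim(ins))[1, ]
    if (b[3] - b[1] < 4 || b[4] - b[2] < 4) next
    # half the steps simulate one FoV move: shift the window by the scaled
    # step in a random direction; the mask channel then carries the
    # previous segmentation state (the object as segmented so far) instead
    # of the seed
    moved <- mode == "moved"
    bWin <- b
    if (moved) {
      dirs <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0),
                    c(-1, -1), c(0, -1), c(1, -1))
      dd <- dirs[sample(8L, 1L), ]
      stepPx <- roundHalfAway(scaleStep(b[3] - b[1], b[4] - b[2], cfg))
      bWin <- b + c(dd[1] * stepPx[1], dd[2] * stepPx[2],
                    dd[1] * stepPx[1], dd[2] * stepPx[2])
      if (bWin[1] < -(b[3] - b[1]) / 2 || bWin[2] < -(b[4] - b[2]) / 2 ||
          bWin[3] > ncol(ins) + (b[3] - b[1]) / 2 ||
          bWin[4] > nrow(ins) + (b[4] - b[2]) / 2) { bWin <- b; moved <- FALSE }
    }
    lv <- assignLevel(bWin, minLevel = cfg$roiMinLevel)
    feat <- roiAlign(pyramids[[pick[1]]][[as.character(lv)]], bWin, 2^lv,
                     outSize = cfg$s)
    # ground-truth local mask: nearest-neighbour keeps it binary
    truth <- (cropTo33(m, bWin, nearest = TRUE) > 0.5) * 1
    maskIn <- if (moved) {
      # previous state: the object as already segmented in the pre-move
      # window, seen from the new window (bilinear on probabilities)
      cropTo33(m * 0.95, bWin, nearest = FALSE)
    } else if (mode == "feedback") {
      segForward(feat, initSeedMask(cfg), weights)  # feedback iteration
    } else initSeedMask(cfg)
    cfgStep <- cfg
    if (st > 2L * steps %/% 3L) cfgStep$lr <- cfg$lr / 10
    r <- segTrainStep(feat, maskIn, truth, weights, state, cfgStep)
    weights <- r$weights; state <- r$state
    trace[st] <- r$loss
  }
  list(weights = weights, lossTrace = trace)
}

#' Segment mitochondria on every slice of a stack
#'
#' Detection, recursive FoV segmentation and canvas merging per slice.
#'
#' @param stack an [ImageStack-class].
#' @param detWeights,segWeights trained weights.
#' @param detCfg,segCfg configurations.
#' @return list with `instances` (z, y, x) integer array and `prob`
#'   (z, y, x) pooled foreground probability array.
#' @export
predictMito <- function(stack, detWeights, segWeights,
                        detCfg = tinyDetectorConfig(),
                        segCfg = segmenterConfig()) {
  v <- voxels(stack); d <- dim(v)
  inst <- array(0L, d); prob <- array(0, d)
  for (z in seq_len(d[1])) {
    img <- v[z, , ]
    boxes <- predictBoxes(img, detWeights, detCfg, sliceIndex = z - 1L)
    if (nrow(boxes) == 0L) next
    pyr <- buildPyramid(img, detWeights)
    fov <- runFovInference(img, boxes, segCfg, pyramid = pyr,
                           segWeights = segWeights)
    inst[z, , ] <- canvasesToInstances(fov, d[2:3], segCfg)
    for (r in fov) prob[z, , ] <- pmax(prob[z, , ], r$canvas)
  }
  list(instances = inst, prob = prob)
}
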