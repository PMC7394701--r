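# Seeded synthetic EM phantoms with paired ground truth.
#
# The phantoms emulate the appearance that drives the pipeline: dark-rimmed
# elliptical mitochondria spanning many serial sections, thin curvilinear ER
# tubules, and a closed nuclear-membrane shell around a nucleus interior,
# over a textured noisy background.  They are the package's test bed; real
# EM texture (vesicles, Golgi, membrane substructure) is out of scope.

#' Phantom generator configuration
#'
#' @param shape volume shape (nz, ny, nx).
#' @param spacingNm voxel spacing (sz, sy, sx) nm; the serial-section
#'   default is strongly anisotropic.
#' @param nMito number of mitochondrion instances.
#' @param mitoRadiusRangeVx in-plane semi-axis range, xy voxels.
#' @param mitoZspanRange range of occupied slice counts per mitochondrion.
#' @param nErTubules number of ER tubule walks.
#' @param erThicknessVx ER tubule half-thickness in voxels.
#' @param nucleus `TRUE` for an auto-placed nucleus, `NULL`/`FALSE` for
#'   none, or `list(center = c(y, x), radius)` (0-based voxel coords).
#' @param rimDarkness intensity drop of the mitochondrial double membrane
#'   relative to background.
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param textureAmp amplitude of the smooth background texture field.
#' @param seed integer; fully determines the phantom.
#' @return a `PhantomConfig` list.
#' @export
phantomConfig <- function(shape = c(20L, 128L, 128L),
                          spacingNm = c(50, 3, 3),
                          nMito = 4L,
                          mitoRadiusRangeVx = c(6, 12),
                          mitoZspanRange = c(15L, 20L),
                          nErTubules = 3L,
                          erThicknessVx = 1L,
                          nucleus = TRUE,
                          rimDarkness = 0.4,
                          noiseSigma = 0.035,
                          textureAmp = 0.05,
                          seed = 1L) {
  stopifnot(nMito >= 0L, nErTubules >= 0L, mitoRadiusRangeVx[1] >= 1,
            mitoZspanRange[1] >= 1L, mitoZspanRange[2] <= shape[1])
  cfg <- list(shape = as.integer(shape), spacingNm = as.numeric(spacingNm),
              nMito = as.integer(nMito),
              mitoRadiusRangeVx = mitoRadiusRangeVx,
              mitoZspanRange = as.integer(mitoZspanRange),
              nErTubules = as.integer(nErTubules),
              erThicknessVx = erThicknessVx,
              nucleus = nucleus, rimDarkness = rimDarkness,
              noiseSigma = noiseSigma, textureAmp = textureAmp,
              seed = as.integer(seed))
  class(cfg) <- "PhantomConfig"
  cfg
}

# smooth per-slice texture field: coarse white noise upsampled bilinearly
.textureSlice <- function(ny, nx, amp) {
  cy <- max(2L, ny %/% 16L); cx <- max(2L, nx %/% 16L)
  coarse <- matrix(rnorm(cy * cx), cy, cx)
  up <- EBImage::resize(coarse, w = ny, h = nx)
  amp * up / max(1e-9, sd(up))
}

# squared in-plane elliptical distance for a rotated ellipse
.ellipseDist2 <- function(ny, nx, cy, cx, a, b, theta) {
  ym <- matrix(seq_len(ny) - 1 - cy, ny, nx)
  xm <- matrix(seq_len(nx) - 1 - cx, ny, nx, byrow = TRUE)
  u <- cos(theta) * xm + sin(theta) * ym
  v <- -sin(theta) * xm + cos(theta) * ym
  (u / a)^2 + (v / b)^2
}

#' Generate a phantom EM stack with paired ground truth
#'
#' Mitochondria are rendered per slice as rotated ellipses with a dark
#' 2-voxel rim and a lighter matrix, following an ellipsoidal z-profile with
#' slow in-plane drift; ER tubules are thin random walks; an optional
#' nucleus is a disk stack whose 2-voxel boundary shell is the nuclear
#' membrane class.  The four truth classes are pairwise disjoint.  Objects
#' that cannot be placed disjointly within a bounded number of attempts are
#' dropped with a warning.
#'
#' @param config a [phantomConfig()].
#' @return `list(stack = ImageStack, truth = PhantomTruth, placedMito = n)`.
#' @export
generatePhantom <- function(config = phantomConfig()) {
  set.seed(config$seed)
  d <- config$shape; nz <- d[1]; ny <- d[2]; nx <- d[3]
  img <- array(0.65, d)
  mito <- array(0L, d)
  er <- array(FALSE, d)
  nucMem <- array(FALSE, d)
  nucInt <- array(FALSE, d)

  for (z in seq_len(nz))
    img[z, , ] <- img[z, , ] + .textureSlice(ny, nx, config$textureAmp)

  # nucleus: disk stack in a corner quadrant
  nuc <- config$nucleus
  if (isTRUE(nuc)) {
    r <- round(0.22 * min(ny, nx))
    nuc <- list(center = c(ny - 1 - r - 2, r + 2), radius = r)
  }
  if (is.list(nuc)) {
    dd <- .ellipseDist2(ny, nx, nuc$center[1], nuc$center[2],
                        nuc$radius, nuc$radius, 0)
    mem2d <- dd <= 1 & dd > ((nuc$radius - 2) / nuc$radius)^2
    int2d <- dd <= ((nuc$radius - 2) / nuc$radius)^2
    for (z in seq_len(nz)) {
      nucMem[z, , ] <- mem2d
      nucInt[z, , ] <- int2d
      sl <- img[z, , ]
      sl[mem2d] <- 0.22
      sl[int2d] <- 0.78 + 0.3 * config$textureAmp *
        matrix(rnorm(ny * nx), ny, nx)[int2d]
      img[z, , ] <- sl
    }
  }
  occupied <- nucMem | nucInt

  # mitochondria
  placed <- 0L
  for (i in seq_len(config$nMito)) {
    ok <- FALSE
    for (attempt in 1:25) {
      a <- runif(1, config$mitoRadiusRangeVx[1], config$mitoRadiusRangeVx[2])
      b <- runif(1, config$mitoRadiusRangeVx[1], min(a, config$mitoRadiusRangeVx[2]))
      theta <- runif(1, 0, pi)
      span <- sample(config$mitoZspanRange[1]:config$mitoZspanRange[2], 1)
      z0 <- sample(0:(nz - span), 1)
      cy <- runif(1, a + 3, ny - a - 4)
      cx <- runif(1, a + 3, nx - a - 4)
      driftY <- runif(1, -0.4, 0.4); driftX <- runif(1, -0.4, 0.4)
      vox <- vector("list", span)
      clash <- FALSE
      for (k in seq_len(span)) {
        t <- if (span > 1) (2 * (k - 1) / (span - 1) - 1) else 0
        sc <- sqrt(pmax(1 - 0.75 * t^2, 0.2))
        dd <- .ellipseDist2(ny, nx, cy + driftY * (k - 1), cx + driftX * (k - 1),
                            a * sc, b * sc, theta)
        inside <- dd <= 1
        if (!any(inside)) { clash <- TRUE; break }
        # check a +-2 slice window so distinct instances never overlap in
        # xy at nearby z (keeps ground-truth 3D linking unambiguous)
        zwin <- max(1L, z0 + k - 2L):min(nz, z0 + k + 2L)
        occWin <- if (length(zwin) == 1L) occupied[zwin, , ] else
          apply(occupied[zwin, , , drop = FALSE], c(2, 3), any)
        if (any(occWin[inside])) { clash <- TRUE; break }
        vox[[k]] <- list(inside = inside, dd = dd)
      }
      if (clash) next
      # render
      for (k in seq_len(span)) {
        z <- z0 + k
        inside <- vox[[k]]$inside; dd <- vox[[k]]$dd
        rim <- inside & dd > (1 - 2.2 / max(a, 3))^2
        sl <- img[z, , ]
        sl[inside] <- 0.5 + 0.5 * config$textureAmp *
          matrix(rnorm(ny * nx), ny, nx)[inside]
        sl[rim] <- 0.65 - config$rimDarkness
        img[z, , ] <- sl
        m <- mito[z, , ]; m[inside] <- placed + 1L; mito[z, , ] <- m
        o <- occupied[z, , ]; o[inside] <- TRUE; occupied[z, , ] <- o
      }
      placed <- placed + 1L
      ok <- TRUE
      break
    }
    if (!ok) warning(sprintf("mitochondrion %d could not be placed disjointly", i))
  }

  # ER tubules: 3D random walks, voxelized thin; never overwrite occupied,
  # and keep a 2-voxel clearance from the nuclear classes so the
  # membrane/ER relabeling split stays well defined
  nucClear <- nucMem | nucInt
  if (any(nucClear)) {
    br <- EBImage::makeBrush(5L, "disc")
    for (z in seq_len(nz))
      nucClear[z, , ] <- EBImage::dilate(
        matrix(as.numeric(nucClear[z, , ]), ny, nx), br) > 0
  }
  erBlocked <- occupied | nucClear
  for (i in seq_len(config$nErTubules)) {
    py <- runif(1, 4, ny - 5); px <- runif(1, 4, nx - 5)
    pz <- sample(seq_len(nz), 1)
    ang <- runif(1, 0, 2 * pi)
    nsteps <- 40L + sample(0:30, 1)
    th <- config$erThicknessVx
    for (s in seq_len(nsteps)) {
      ang <- ang + rnorm(1, 0, 0.35)
      py <- .clamp(py + 1.4 * sin(ang), 2, ny - 3)
      px <- .clamp(px + 1.4 * cos(ang), 2, nx - 3)
      if (runif(1) < 0.08) pz <- .clamp(pz + sample(c(-1L, 1L), 1), 1, nz)
      ys <- .clamp(round(py) + (-th:th), 0, ny - 1)
      xs <- .clamp(round(px) + (-th:th), 0, nx - 1)
      for (yy in ys) for (xx in xs) {
        if ((yy - py)^2 + (xx - px)^2 <= th^2 + 0.5 &&
            !erBlocked[pz, yy + 1, xx + 1]) {
          er[pz, yy + 1, xx + 1] <- TRUE
          img[pz, yy + 1, xx + 1] <- 0.25
        }
      }
    }
  }

  img <- img + array(rnorm(prod(d), 0, config$noiseSigma), d)
  img <- .clamp(img, 0, 1)

  truth <- new("PhantomTruth", mito = LabelVolume(mito), er = er,
               nucMembrane = nucMem, nucInterior = nucInt)
  list(stack = new("ImageStack", voxels = img,
                   spacingNm = config$spacingNm, origin = c(0L, 0L, 0L)),
       truth = truth, placedMito = placed)
}

#' Jointly augment an image/label slice pair
#'
#' The same geometric transform (right-angle rotation and flips by default)
#' is applied to both; additive Gaussian noise goes on the image only, so
#' labels stay integer-valued and the set of instance ids is conserved.
#'
#' @param image 2D numeric matrix.
#' @param labels 2D integer matrix, same shape.
#' @param seed integer seed.
#' @param noiseSigma Gaussian noise sd added to the image.
#' @param arbitraryAngle if `TRUE`, a uniform random rotation is applied
#'   (bilinear on the image, nearest-neighbour on labels) instead of a
#'   right-angle one.
#' @param rotK,flipH,flipV optional explicit transform (rotation quarter
#'   turns and flips); when given they override the seeded draw.
#' @return `list(image =, labels =)`.
#' @export
augmentPair <- function(image, labels, seed, noiseSigma = 0.03,
                        arbitraryAngle = FALSE,
                        rotK = NULL, flipH = NULL, flipV = NULL) {
  stopifnot(identical(dim(image), dim(labels)))
  set.seed(seed)
  k <- if (is.null(rotK)) sample(0:3, 1) else as.integer(rotK)
  flipH <- if (is.null(flipH)) runif(1) < 0.5 else isTRUE(flipH)
  flipV <- if (is.null(flipV)) runif(1) < 0.5 else isTRUE(flipV)
  rot90 <- function(m, times) {
    for (i in seq_len(times %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
    m
  }
  tf <- function(m, nearest) {
    if (arbitraryAngle) {
      ang <- runif(1, 0, 360)
      m <- EBImage::rotate(m, ang, output.dim = dim(m), output.origin = NULL,
                           filter = if (nearest) "none" else "bilinear")
      m <- matrix(as.numeric(m), dim(image)[1], dim(image)[2])
    } else m <- rot90(m, k)
    if (flipH) m <- m[, ncol(m):1, drop = FALSE]
    if (flipV) m <- m[nrow(m):1, , drop = FALSE]
    m
  }
  if (arbitraryAngle) {
    # one shared angle: draw it once, reuse via the same seed
    set.seed(seed); img2 <- tf(image, nearest = FALSE)
    set.seed(seed); lab2 <- tf(labels, nearest = TRUE)
  } else {
    img2 <- tf(image, nearest = FALSE)
    lab2 <- tf(labels, nearest = TRUE)
  }
  img2 <- .clamp(img2 + matrix(rnorm(length(img2), 0, noiseSigma),
                               nrow(img2), ncol(img2)), 0, 1)
  list(image = img2, labels = matrix(as.integer(round(lab2)),
                                     nrow(lab2), ncol(lab2)))
}
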