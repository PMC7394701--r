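# Volume I/O, histogram matching, patch tiling.
#
# Supported containers: multi-page TIFF ("tiff_stack") and zero-padded
# numbered PNG/TIFF series ("image_series").  Label volumes use the same
# containers as 16-bit integer images.

.IO_FORMATS <- c("tiff_stack", "image_series", "hdf5")

.asGray <- function(m) {
  # collapse RGB(A) pages to a single channel
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Read a serial-section image stack
#'
#' @param path a multi-page TIFF file, or a directory of numbered
#'   single-slice PNG/TIFF files (sorted by filename).
#' @param format one of `"tiff_stack"`, `"image_series"`; `"hdf5"` is part
#'   of the declared interface but not available in this build.
#' @param spacingNm voxel spacing (sz, sy, sx) in nm used when the container
#'   carries no spacing metadata (TIFF/PNG do not).
#' @return An [ImageStack-class] of shape (n_slices, H, W).
#' @export
readStack <- function(path, format = c("tiff_stack", "image_series", "hdf5"),
                      spacingNm = c(50, 3, 3)) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("format 'hdf5' is not supported in this build; ",
         "use 'tiff_stack' or 'image_series'")
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, .asGray)
  } else {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF slices found under ", path)
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE))
        .asGray(png::readPNG(f))
      else .asGray(tiff::readTIFF(f))
    })
  }
  d1 <- dim(pages[[1L]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf(
        "inconsistent slice shapes: slice %d is %dx%d, expected %dx%d",
        i - 1L, dim(pages[[i]])[1], dim(pages[[i]])[2], d1[1], d1[2]))
  v <- array(0, dim = c(length(pages), d1[1], d1[2]))
  for (i in seq_along(pages)) v[i, , ] <- pages[[i]]
  new("ImageStack", voxels = v, spacingNm = as.numeric(spacingNm),
      origin = c(0L, 0L, 0L))
}

#' Write an image stack or label volume
#'
#' Intensities are written as 8-bit; [LabelVolume-class] objects as 16-bit
#' (supports up to 65535 instances).
#'
#' @param x an [ImageStack-class] or [LabelVolume-class].
#' @param path output TIFF path (`tiff_stack`) or directory (`image_series`).
#' @param format `"tiff_stack"` or `"image_series"`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(x, path, format = c("tiff_stack", "image_series")) {
  format <- match.arg(format)
  if (is(x, "LabelVolume")) {
    v <- x@labels
    if (max(v) > 65535L) stop("more than 65535 instances cannot be written")
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
    bits <- 16L
  } else {
    v <- x@voxels
    pages <- lapply(seq_len(dim(v)[1]), function(z)
      round(pmin(pmax(v[z, , ], 0), 1) * 255) / 255)
    bits <- 8L
  }
  if (format == "tiff_stack") {
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_along(pages))
      png::writePNG(pages[[z]],
                    file.path(path, sprintf("slice_%04d.png", z - 1L)))
  }
  invisible(path)
}

#' Read a label volume written by [writeStack()]
#' @inheritParams readStack
#' @return A [LabelVolume-class].
#' @export
readLabels <- function(path, format = c("tiff_stack", "image_series")) {
  s <- readStack(path, match.arg(format))
  LabelVolume(array(as.integer(round(s@voxels * 65535)), dim = dim(s@voxels)))
}

#' Histogram matching of one image against a reference
#'
#' Maps intensities of `image` through the classical CDF-inversion rule so
#' that its empirical distribution matches `reference`'s.  Used to keep
#' grayscale statistics consistent across serial sections before network
#' input.  The mapping is monotone, so pixel ranks are never inverted.
#'
#' @param image 2D numeric matrix in [0, 1].
#' @param reference 2D numeric matrix in [0, 1]; a constant reference maps
#'   every pixel to that constant (with a warning).
#' @param nbins quantization bins (256 reproduces 8-bit behaviour).
#' @return matched matrix, same shape as `image`.
#' @export
histogramMatch <- function(image, reference, nbins = 256L) {
  if (length(image) == 0L || length(reference) == 0L)
    stop("image and reference must be non-empty")
  rr <- range(reference)
  if (rr[2] - rr[1] < .Machine$double.eps) {
    warning("constant reference: returning constant image")
    out <- image; out[] <- rr[1]; return(out)
  }
  q <- function(v) pmin(as.integer(floor(v * nbins)), nbins - 1L)
  srcCdf <- cumsum(tabulate(q(image) + 1L, nbins)) / length(image)
  refCounts <- tabulate(q(reference) + 1L, nbins)
  refCdf <- cumsum(refCounts) / length(reference)
  # for each source bin, smallest reference bin whose CDF reaches it
  lut <- findInterval(srcCdf, refCdf, left.open = TRUE) + 1L
  lut <- pmin(lut, nbins)
  out <- image
  out[] <- (lut[q(image) + 1L] - 1L) / (nbins - 1L)
  out
}

#' Match every slice of a stack against one fixed reference slice
#'
#' @param stack an [ImageStack-class].
#' @param reference 2D matrix; default the first slice of `stack`.
#' @return matched [ImageStack-class].
#' @export
matchStack <- function(stack, reference = NULL) {
  v <- stack@voxels
  if (is.null(reference)) reference <- v[1, , ]
  for (z in seq_len(dim(v)[1])) v[z, , ] <- histogramMatch(v[z, , ], reference)
  initialize(stack, voxels = v)
}

# ---- patch tiling ---------------------------------------------------------

#' Define a patch grid over an image
#'
#' Patch origins are placed at multiples of the stride and the final row /
#' column of origins is clamped so patches never extend past the image;
#' together the patches always cover the image.
#'
#' @param imageShape (H, W) of the source image.
#' @param patchShape (h, w) patch size.
#' @param stride (sy, sx); defaults to `patchShape` (no overlap).
#' @return a `PatchGrid` list with the patch origins.
#' @export
patchGrid <- function(imageShape, patchShape, stride = patchShape) {
  if (any(patchShape > imageShape))
    stop(sprintf("patch %dx%d larger than image %dx%d",
                 patchShape[1], patchShape[2], imageShape[1], imageShape[2]))
  starts <- function(n, p, s) {
    o <- seq(0L, max(n - p, 0L), by = s)
    if (o[length(o)] + p < n) o <- c(o, n - p)
    o
  }
  g <- list(imageShape = as.integer(imageShape),
            patchShape = as.integer(patchShape),
            stride = as.integer(stride),
            oy = starts(imageShape[1], patchShape[1], stride[1]),
            ox = starts(imageShape[2], patchShape[2], stride[2]))
  class(g) <- "PatchGrid"
  g
}

#' Cut an image into patches
#' @param image 2D matrix.
#' @param grid a [patchGrid()].
#' @return list of patch matrices, row-major over (oy, ox) origins.
#' @export
tilePatches <- function(image, grid) {
  stopifnot(identical(dim(image), as.integer(grid$imageShape)))
  p <- grid$patchShape
  out <- vector("list", length(grid$oy) * length(grid$ox))
  k <- 1L
  for (y0 in grid$oy) for (x0 in grid$ox) {
    out[[k]] <- image[(y0 + 1L):(y0 + p[1]), (x0 + 1L):(x0 + p[2]), drop = FALSE]
    k <- k + 1L
  }
  out
}

#' Stitch patches back into an image
#'
#' Exact inverse of [tilePatches()] for non-overlapping grids; overlapping
#' regions are averaged with per-pixel coverage weights.
#'
#' @param patches list from [tilePatches()] (same order).
#' @param grid the [patchGrid()] used to cut them.
#' @return 2D matrix of shape `grid$imageShape`.
#' @export
stitchPatches <- function(patches, grid) {
  acc <- matrix(0, grid$imageShape[1], grid$imageShape[2])
  wt <- matrix(0, grid$imageShape[1], grid$imageShape[2])
  p <- grid$patchShape
  k <- 1L
  for (y0 in grid$oy) for (x0 in grid$ox) {
    ys <- (y0 + 1L):(y0 + p[1]); xs <- (x0 + 1L):(x0 + p[2])
    acc[ys, xs] <- acc[ys, xs] + patches[[k]]
    wt[ys, xs] <- wt[ys, xs] + 1
    k <- k + 1L
  }
  acc / wt
}
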