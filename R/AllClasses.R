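#' @import methods
#' @importFrom stats lm predict coef median quantile rnorm runif rbinom sd var dnorm
#' @importFrom utils head tail
NULL

#' ImageStack: a 3D grayscale EM volume with physical voxel spacing
#'
#' Voxels are stored as a numeric array in (z, y, x) order with intensities
#' in [0, 1] (8-bit data are mapped to k/255).  Spacing is (sz, sy, sx) in
#' nanometres; serial-section EM is strongly anisotropic (default
#' 50 x 3 x 3 nm).  All coordinates in the package are 0-based with
#' half-open extents.
#'
#' @slot voxels numeric array, dim (nz, ny, nx), values in [0, 1].
#' @slot spacingNm numeric length-3, (sz, sy, sx), strictly positive.
#' @slot origin integer length-3, (z0, y0, x0) offsets of voxel (0,0,0).
#' @export
setClass("ImageStack",
  representation(voxels = "array", spacingNm = "numeric", origin = "integer"),
  prototype(spacingNm = c(50, 3, 3), origin = c(0L, 0L, 0L))
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array (z, y, x)")
  if (any(dim(v) < 1L)) return("all dimensions must be >= 1")
  if (length(object@spacingNm) != 3L || any(object@spacingNm <= 0))
    return("spacingNm must be 3 strictly positive values (sz, sy, sx)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  rng <- range(v)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("intensities must lie in [0, 1]")
  TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array (z, y, x) in [0,1], or integer 0..255
#'   (rescaled to [0,1]).
#' @param spacingNm voxel spacing (sz, sy, sx) in nm.
#' @param origin integer offsets (z0, y0, x0).
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(voxels, spacingNm = c(50, 3, 3),
                       origin = c(0L, 0L, 0L)) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (is.integer(voxels) || max(voxels, na.rm = TRUE) > 1 + 1e-9)
    voxels <- array(as.numeric(voxels) / 255, dim = dim(voxels))
  new("ImageStack", voxels = voxels, spacingNm = as.numeric(spacingNm),
      origin = as.integer(origin))
}

#' LabelVolume: 3D grid of non-negative integer instance labels
#'
#' Label 0 is reserved for background.
#'
#' @slot labels integer array, dim (nz, ny, nx), values >= 0.
#' @export
setClass("LabelVolume", representation(labels = "array"))

setValidity("LabelVolume", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L) return("labels must be a 3D array (z, y, x)")
  if (!is.integer(l)) return("labels must be integer")
  if (min(l) < 0L) return("labels must be non-negative (0 = background)")
  TRUE
})

#' Construct a LabelVolume
#' @param labels 3D integer-valued array (z, y, x); coerced to integer.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(labels) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(1L, dim(labels)))
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels)
}

#' PhantomTruth: paired ground truth for a synthetic EM phantom
#'
#' The four foreground classes (mitochondrion instances, ER, nuclear
#' membrane, nucleus interior) are pairwise disjoint by construction.
#'
#' @slot mito a [LabelVolume-class] of mitochondrion instances.
#' @slot er logical array, ER tubule mask.
#' @slot nucMembrane logical array, nuclear membrane shell.
#' @slot nucInterior logical array, nucleus interior.
#' @export
setClass("PhantomTruth",
  representation(mito = "LabelVolume", er = "array",
                 nucMembrane = "array", nucInterior = "array"))

setValidity("PhantomTruth", function(object) {
  d <- dim(object@mito@labels)
  for (nm in c("er", "nucMembrane", "nucInterior")) {
    a <- slot(object, nm)
    if (!identical(dim(a), d)) return(sprintf("%s shape mismatch", nm))
    if (!is.logical(a)) return(sprintf("%s must be logical", nm))
  }
  m <- object@mito@labels > 0L
  if (any(m & object@er) || any(m & object@nucMembrane) ||
      any(m & object@nucInterior) || any(object@er & object@nucMembrane) ||
      any(object@er & object@nucInterior) ||
      any(object@nucMembrane & object@nucInterior))
    return("foreground classes must be pairwise disjoint")
  TRUE
})

#' Organelle3D: one reconstructed 3D object as linked per-slice regions
#'
#' @slot id integer object id.
#' @slot regions list of per-slice regions, each a list with elements
#'   `slice` (0-based z), `pixels` (n x 2 integer matrix of 0-based (y, x)),
#'   `centroid` (length-2 (y, x)), `area` (pixel count); ordered by slice.
#' @slot spacingNm voxel spacing (sz, sy, sx) in nm.
#' @export
setClass("Organelle3D",
  representation(id = "integer", regions = "list", spacingNm = "numeric"))

setValidity("Organelle3D", function(object) {
  if (length(object@regions) == 0L) return("object must have >= 1 region")
  z <- vapply(object@regions, function(r) r$slice, 0L)
  if (is.unsorted(z)) return("regions must be ordered by slice")
  for (r in object@regions)
    if (nrow(r$pixels) == 0L) return("regions must be non-empty")
  TRUE
})

#' Skeleton: smoothed 3D centreline of an organelle
#'
#' @slot points n x 3 matrix of (z, y, x) positions in nm.
#' @slot coeffs list of per-axis polynomial coefficients (may be empty for
#'   raw skeletons).
#' @slot arcLengthNm total arc length in nm.
#' @export
setClass("Skeleton",
  representation(points = "matrix", coeffs = "list", arcLengthNm = "numeric"))

# ---- accessors ------------------------------------------------------------

#' @describeIn ImageStack voxel array accessor
#' @param x an object
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @describeIn ImageStack spacing accessor (nm, (sz, sy, sx))
#' @export
setGeneric("spacingNm", function(x) standardGeneric("spacingNm"))
#' @export
setMethod("spacingNm", "ImageStack", function(x) x@spacingNm)

#' @describeIn LabelVolume label array accessor
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))
#' @export
setMethod("labels3d", "LabelVolume", function(x) x@labels)

#' @describeIn LabelVolume the set of nonzero instance ids present
#' @export
setGeneric("idSet", function(x) standardGeneric("idSet"))
#' @export
setMethod("idSet", "LabelVolume", function(x) {
  u <- sort(unique(as.vector(x@labels)))
  u[u != 0L]
})

#' @describeIn Organelle3D number of distinct occupied slices (the
#'   z-direction "length" used by the reconstruction filter)
#' @export
setGeneric("zLength", function(x) standardGeneric("zLength"))
#' @export
setMethod("zLength", "Organelle3D", function(x)
  length(unique(vapply(x@regions, function(r) r$slice, 0L))))

#' @describeIn Organelle3D total voxel count
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @export
setMethod("voxelCount", "Organelle3D", function(x)
  sum(vapply(x@regions, function(r) nrow(r$pixels), 0L)))

#' @describeIn Skeleton skeleton points accessor ((z, y, x) nm)
#' @export
setGeneric("skeletonPoints", function(x) standardGeneric("skeletonPoints"))
#' @export
setMethod("skeletonPoints", "Skeleton", function(x) x@points)

# ---- show methods ---------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d slices of %d x %d (y x x), spacing %g x %g x %g nm\n",
              d[1], d[2], d[3], object@spacingNm[1], object@spacingNm[2],
              object@spacingNm[3]))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume: %d x %d x %d (z,y,x), %d instances\n",
              d[1], d[2], d[3], length(idSet(object))))
})

setMethod("show", "Organelle3D", function(object) {
  cat(sprintf("Organelle3D #%d: %d regions over %d slices, %d voxels\n",
              object@id, length(object@regions), zLength(object),
              voxelCount(object)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d points, arc length %.1f nm\n",
              nrow(object@points), object@arcLengthNm))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d mitochondria, ER %d vx, membrane %d vx, interior %d vx\n",
              length(idSet(object@mito)), sum(object@er),
              sum(object@nucMembrane), sum(object@nucInterior)))
})
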