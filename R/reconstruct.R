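# 2D -> 3D reconstruction: link per-slice instances across the anisotropic
# z-axis by overlap, rectify local errors morphologically and from slice
# context, and filter objects by their z-length.

# per-slice regions from an integer instance map: list of
# list(slice, id, pixels (n x 2, 0-based (y, x)), area, centroid)
#' @keywords internal
sliceRegions <- function(instMap, slice) {
  ids <- setdiff(sort(unique(as.vector(instMap))), 0L)
  lapply(ids, function(id) {
    w <- which(instMap == id, arr.ind = TRUE)
    list(slice = as.integer(slice), id = as.integer(id),
         pixels = cbind(y = w[, 1] - 1L, x = w[, 2] - 1L),
         area = nrow(w),
         centroid = c(mean(w[, 1]) - 1, mean(w[, 2]) - 1))
  })
}

# overlap pixel count between two pixel sets on an (H, W) grid
.overlapCount <- function(pa, pb, W) {
  length(intersect(pa[, 1] * W + pa[, 2], pb[, 1] * W + pb[, 2]))
}

#' Link per-slice 2D instances into 3D objects
#'
#' Regions on consecutive slices are linked when their IoU is at least
#' `tau` or the containment overlap (intersection over the smaller area)
#' is at least `contain`; candidate pairs are matched greedily by
#' descending IoU, one-to-one per slice pair.  Regions left unmatched may
#' link across up to `gap` missing slices under the same criterion
#' (multilayer context fusion).  Connected components of the link graph
#' become [Organelle3D-class] objects.  The procedure is deterministic and
#' invariant to permutations of the input instance ids.
#'
#' @param instancesPerSlice list of integer instance matrices (one per
#'   slice, 0 = background), or a (z, y, x) integer array.
#' @param tau IoU linking threshold.
#' @param contain containment-overlap threshold.
#' @param gap maximum number of missing slices a link may bridge.
#' @param spacingNm voxel spacing stored in the objects.
#' @return list of [Organelle3D-class], ordered by first slice then id.
#' @export
linkSlices <- function(instancesPerSlice, tau = 0.3, contain = 0.5,
                       gap = 1L, spacingNm = c(50, 3, 3)) {
  if (is.array(instancesPerSlice) && length(dim(instancesPerSlice)) == 3L)
    instancesPerSlice <- lapply(seq_len(dim(instancesPerSlice)[1]),
                                function(z) instancesPerSlice[z, , ])
  nz <- length(instancesPerSlice)
  stopifnot(nz >= 1L)
  W <- ncol(instancesPerSlice[[1]])
  regs <- list()
  bySlice <- vector("list", nz)
  for (z in seq_len(nz)) {
    rs <- sliceRegions(instancesPerSlice[[z]], z - 1L)
    idx <- integer(length(rs))
    for (i in seq_along(rs)) {
      regs[[length(regs) + 1L]] <- rs[[i]]
      idx[i] <- length(regs)
    }
    bySlice[[z]] <- idx
  }
  nReg <- length(regs)
  if (nReg == 0L) return(list())

  # candidate links between slice z and z + dz
  pairScores <- function(z, dz) {
    ia <- bySlice[[z]]; ib <- bySlice[[z + dz]]
    if (length(ia) == 0L || length(ib) == 0L) return(NULL)
    out <- NULL
    for (a in ia) for (b in ib) {
      ov <- .overlapCount(regs[[a]]$pixels, regs[[b]]$pixels, W)
      if (ov == 0L) next
      iou <- ov / (regs[[a]]$area + regs[[b]]$area - ov)
      cont <- ov / min(regs[[a]]$area, regs[[b]]$area)
      if (iou >= tau || cont >= contain)
        out <- rbind(out, c(a, b, iou))
    }
    out
  }

  edges <- NULL
  linkedFwd <- rep(FALSE, nReg); linkedBwd <- rep(FALSE, nReg)
  for (z in seq_len(nz - 1L)) {
    ps <- pairScores(z, 1L)
    if (is.null(ps)) next
    ps <- ps[order(-ps[, 3], ps[, 1], ps[, 2]), , drop = FALSE]
    usedA <- integer(0); usedB <- integer(0)
    for (r in seq_len(nrow(ps))) {
      a <- ps[r, 1]; b <- ps[r, 2]
      if (a %in% usedA || b %in% usedB) next
      usedA <- c(usedA, a); usedB <- c(usedB, b)
      edges <- rbind(edges, c(a, b))
      linkedFwd[a] <- TRUE; linkedBwd[b] <- TRUE
    }
  }
  if (gap >= 1L && nz > 2L) for (dz in 2L:(gap + 1L)) {
    if (nz <= dz) break
    for (z in seq_len(nz - dz)) {
      ps <- pairScores(z, dz)
      if (is.null(ps)) next
      ps <- ps[order(-ps[, 3], ps[, 1], ps[, 2]), , drop = FALSE]
      usedA <- integer(0); usedB <- integer(0)
      for (r in seq_len(nrow(ps))) {
        a <- ps[r, 1]; b <- ps[r, 2]
        if (linkedFwd[a] || linkedBwd[b]) next
        if (a %in% usedA || b %in% usedB) next
        usedA <- c(usedA, a); usedB <- c(usedB, b)
        edges <- rbind(edges, c(a, b))
        linkedFwd[a] <- TRUE; linkedBwd[b] <- TRUE
      }
    }
  }

  g <- igraph::make_empty_graph(n = nReg, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out <- list()
  for (cid in sort(unique(memb))) {
    members <- which(memb == cid)
    rl <- regs[members]
    rl <- rl[order(vapply(rl, function(r) r$slice, 0L))]
    out[[length(out) + 1L]] <- new("Organelle3D",
      id = length(out) + 1L, regions = rl, spacingNm = as.numeric(spacingNm))
  }
  # deterministic order: by first slice, then first-region centroid
  ord <- order(vapply(out, function(o) o@regions[[1]]$slice, 0L),
               vapply(out, function(o) o@regions[[1]]$centroid[1], 0),
               vapply(out, function(o) o@regions[[1]]$centroid[2], 0))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]@id <- as.integer(i)
  out
}

# region pixels -> cropped binary matrix + offset
.regionCrop <- function(pixels, margin) {
  y0 <- min(pixels[, 1]) - margin; x0 <- min(pixels[, 2]) - margin
  h <- max(pixels[, 1]) - y0 + margin + 1L
  w <- max(pixels[, 2]) - x0 + margin + 1L
  m <- matrix(0, h, w)
  m[cbind(pixels[, 1] - y0 + 1L, pixels[, 2] - x0 + 1L)] <- 1
  list(m = m, y0 = y0, x0 = x0)
}

.cropToPixels <- function(m, y0, x0, bounds = NULL) {
  w <- which(m > 0, arr.ind = TRUE)
  px <- cbind(y = w[, 1] + y0 - 1L, x = w[, 2] + x0 - 1L)
  if (!is.null(bounds))
    px <- px[px[, 1] >= 0L & px[, 1] < bounds[1] &
               px[, 2] >= 0L & px[, 2] < bounds[2], , drop = FALSE]
  px
}

# dilated intersection of two neighbour regions (the gap-bridging fill)
.bridgeRegions <- function(rA, rB, radius, bounds) {
  allPix <- rbind(rA$pixels, rB$pixels)
  y0 <- min(allPix[, 1]) - radius - 1L; x0 <- min(allPix[, 2]) - radius - 1L
  h <- max(allPix[, 1]) - y0 + radius + 2L
  w <- max(allPix[, 2]) - x0 + radius + 2L
  mA <- matrix(0, h, w); mB <- matrix(0, h, w)
  mA[cbind(rA$pixels[, 1] - y0 + 1L, rA$pixels[, 2] - x0 + 1L)] <- 1
  mB[cbind(rB$pixels[, 1] - y0 + 1L, rB$pixels[, 2] - x0 + 1L)] <- 1
  br <- EBImage::makeBrush(2L * radius + 1L, "disc")
  inter <- (EBImage::dilate(mA, br) > 0) & (EBImage::dilate(mB, br) > 0)
  # erode back so the interpolated shape matches the neighbours' scale
  er <- EBImage::erode(inter * 1, br) > 0
  if (any(er)) inter <- er
  if (!any(inter)) inter <- (mA > 0) & (mB > 0)
  if (!any(inter)) return(NULL)
  .cropToPixels(inter * 1, y0, x0, bounds)
}

#' Rectify reconstructed objects
#'
#' Three local corrections, in order: (a) morphological closing then
#' opening with a small disc on every per-slice region; (b) one-slice gaps
#' bridged by the linker are filled with the dilated intersection of the
#' two neighbouring regions; (c) regions whose area deviates from the
#' object's median by more than `areaFactor` in either direction are
#' replaced by the same neighbour interpolation.  Clean objects pass
#' through unchanged.
#'
#' @param objects list of [Organelle3D-class] from [linkSlices()].
#' @param bounds (H, W) slice shape, used to clip filled regions.
#' @param diskRadius structuring-element radius (px).
#' @param areaFactor outlier threshold on area ratio to the object median.
#' @return rectified object list (objects whose every region vanished are
#'   dropped).
#' @export
rectifyObjects <- function(objects, bounds, diskRadius = 2L,
                           areaFactor = 5) {
  br <- EBImage::makeBrush(2L * diskRadius + 1L, "disc")
  out <- list()
  for (obj in objects) {
    regs <- obj@regions
    # (a) hole closing then opening-by-reconstruction per region: removes
    # detached debris and fills enclosed holes while leaving a clean
    # region bit-exact (plain closing/opening would resculpt discrete
    # boundaries and is not idempotent on clean shapes)
    kept <- list()
    for (r in regs) {
      cr <- .regionCrop(r$pixels, diskRadius + 1L)
      m <- EBImage::fillHull(cr$m)
      seed <- EBImage::erode(m, br)
      if (any(seed > 0)) {
        # geodesic reconstruction of the erosion under m
        repeat {
          grown <- (EBImage::dilate(seed, br) > 0) & (m > 0)
          if (sum(grown) == sum(seed > 0)) break
          seed <- grown * 1
        }
        m <- (seed > 0) * 1
      }
      px <- .cropToPixels(m, cr$y0, cr$x0, bounds)
      if (nrow(px) == 0L) next
      r$pixels <- px; r$area <- nrow(px)
      r$centroid <- c(mean(px[, 1]), mean(px[, 2]))
      kept[[length(kept) + 1L]] <- r
    }
    if (length(kept) == 0L) next
    regs <- kept
    # (c) area outliers -> neighbour interpolation
    areas <- vapply(regs, function(r) r$area, 0)
    med <- median(areas)
    for (i in seq_along(regs)) {
      if (areas[i] <= areaFactor * med && areas[i] >= med / areaFactor) next
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= length(regs)]
      nb <- nb[areas[nb] <= areaFactor * med & areas[nb] >= med / areaFactor]
      if (length(nb) == 2L) {
        px <- .bridgeRegions(regs[[nb[1]]], regs[[nb[2]]], diskRadius, bounds)
      } else if (length(nb) == 1L) {
        px <- regs[[nb[1]]]$pixels
      } else px <- NULL
      if (!is.null(px) && nrow(px) > 0L) {
        regs[[i]]$pixels <- px
        regs[[i]]$area <- nrow(px)
        regs[[i]]$centroid <- c(mean(px[, 1]), mean(px[, 2]))
      }
    }
    # (b) fill one-slice gaps between consecutive regions
    zs <- vapply(regs, function(r) r$slice, 0L)
    filled <- regs
    for (i in seq_len(length(regs) - 1L)) {
      if (zs[i + 1L] - zs[i] == 2L) {
        px <- .bridgeRegions(regs[[i]], regs[[i + 1L]], diskRadius, bounds)
        if (!is.null(px) && nrow(px) > 0L)
          filled[[length(filled) + 1L]] <- list(
            slice = zs[i] + 1L, id = regs[[i]]$id, pixels = px,
            area = nrow(px), centroid = c(mean(px[, 1]), mean(px[, 2])))
      }
    }
    filled <- filled[order(vapply(filled, function(r) r$slice, 0L))]
    obj@regions <- filled
    out[[length(out) + 1L]] <- obj
  }
  for (i in seq_along(out)) out[[i]]@id <- as.integer(i)
  out
}

#' Filter reconstructed objects by z-length
#'
#' Keeps exactly the objects whose number of occupied slices is at least
#' `L`; idempotent.
#'
#' @param objects list of [Organelle3D-class].
#' @param L minimum z-length in slices.
#' @return filtered list (ids renumbered).
#' @export
filterByLength <- function(objects, L = 15L) {
  out <- objects[vapply(objects, zLength, 0L) >= L]
  for (i in seq_along(out)) out[[i]]@id <- as.integer(i)
  out
}

#' Render objects into a 3D instance label volume
#'
#' @param objects list of [Organelle3D-class].
#' @param dims (nz, ny, nx).
#' @return a [LabelVolume-class]; later objects overwrite earlier on
#'   (rare) overlap.
#' @export
objectsToLabelVolume <- function(objects, dims) {
  lab <- array(0L, dims)
  for (obj in objects) for (r in obj@regions) {
    z <- r$slice + 1L
    lab[cbind(z, r$pixels[, 1] + 1L, r$pixels[, 2] + 1L)] <- obj@id
  }
  LabelVolume(lab)
}

#' Binary 3D mask of one object
#' @param obj an [Organelle3D-class]. @param dims (nz, ny, nx).
#' @return logical array.
#' @export
objectMask <- function(obj, dims) {
  m <- array(FALSE, dims)
  for (r in obj@regions)
    m[cbind(r$slice + 1L, r$pixels[, 1] + 1L, r$pixels[, 2] + 1L)] <- TRUE
  m
}

#' Per-object summary table
#' @param objects list of [Organelle3D-class].
#' @return data.frame (id, zStart, zEnd, zLength, voxels).
#' @export
summarizeObjects <- function(objects) {
  data.frame(
    id = vapply(objects, function(o) o@id, 0L),
    zStart = vapply(objects, function(o) o@regions[[1]]$slice, 0L),
    zEnd = vapply(objects, function(o) o@regions[[length(o@regions)]]$slice, 0L),
    zLength = vapply(objects, zLength, 0L),
    voxels = vapply(objects, voxelCount, 0L))
}
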