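# shared fixtures: small phantom configurations and geometric masks built
# in code

tinyPhantom <- function(seed, nz = 20L, side = 64L, nMito = 3L,
                        nucleus = FALSE, nEr = 2L,
                        radius = c(4, 9), zspan = c(15L, 20L)) {
  suppressWarnings(generatePhantom(phantomConfig(
    shape = c(nz, side, side), nMito = nMito,
    mitoRadiusRangeVx = radius, mitoZspanRange = zspan,
    nErTubules = nEr, nucleus = nucleus, seed = seed)))
}

# axis-aligned digital cylinder along z, radius in xy voxels
cylinderMask <- function(nz, side, zFrom, zTo, r, cy = (side + 1) / 2,
                         cx = (side + 1) / 2) {
  m <- array(FALSE, c(nz, side, side))
  ym <- matrix(seq_len(side) - 0.5 - (cy - 0.5), side, side)
  xm <- matrix(seq_len(side) - 0.5 - (cx - 0.5), side, side, byrow = TRUE)
  disk <- (ym^2 + xm^2) <= r^2
  for (z in zFrom:zTo) m[z, , ] <- disk
  m
}

# digital ball with physical radius rNm under spacing sp
ballMask <- function(dims, centerNm, rNm, sp) {
  m <- array(FALSE, dims)
  for (z in seq_len(dims[1])) {
    dz <- (z - 0.5) * sp[1] - centerNm[1]
    rem <- rNm^2 - dz^2
    if (rem <= 0) next
    ym <- (seq_len(dims[2]) - 0.5) * sp[2] - centerNm[2]
    xm <- (seq_len(dims[3]) - 0.5) * sp[3] - centerNm[3]
    m[z, , ] <- outer(ym^2, xm^2, "+") <= rem
  }
  m
}

# ground-truth boxes for one instance slice
gtBoxesOf <- function(instMap) OrganelleEM:::gtBoxesFromInstances(instMap)

# oracle FoV predictor: returns the true local mask of `shape` for a window
oraclePredictor <- function(shape) {
  H <- nrow(shape); W <- ncol(shape)
  function(rect, maskIn) {
    x0 <- max(0L, floor(rect[1])); y0 <- max(0L, floor(rect[2]))
    x1 <- min(W, ceiling(rect[3])); y1 <- min(H, ceiling(rect[4]))
    crop <- shape[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE] * 1
    m <- EBImage::resize(crop, w = 33, h = 33, filter = "none")
    pmin(pmax(matrix(as.numeric(m), 33, 33) * 0.98, 0.01), 0.99)
  }
}
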