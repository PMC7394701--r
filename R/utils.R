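# Shared helpers: connected components (8- and 26-connectivity), Euclidean
# distance transform, small RNG utilities.

#' Label connected components of a 2D mask with 8-connectivity
#'
#' EBImage's \code{bwlabel} is 4-connected; diagonal-touching fragments are
#' merged here through a label-adjacency graph.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents2D <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # pairs of distinct labels touching diagonally
  pr <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    cbind(a[keep], b[keep])
  }
  nr <- nrow(lab); nc <- ncol(lab)
  e <- rbind(
    pr(lab[-nr, -nc], lab[-1, -1]),
    pr(lab[-nr, -1], lab[-1, -nc])
  )
  if (nrow(e) > 0L) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(unique(e)))
    map <- as.integer(factor(igraph::components(g)$membership))
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  lab
}

#' Label connected components of a 3D mask with 26-connectivity
#'
#' Slices are labeled in 2D (8-connectivity) and labels touching across
#' adjacent slices (including diagonally) are merged.
#'
#' @param mask logical 3D array (z, y, x).
#' @return integer 3D array of component labels (0 = background).
#' @export
labelComponents3D <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[1])) {
    lz <- labelComponents2D(mask[z, , ])
    lz[lz > 0L] <- lz[lz > 0L] + offset
    lab[z, , ] <- lz
    offset <- max(offset, max(lz))
  }
  n <- offset
  if (n <= 1L || d[1] == 1L) return(lab)
  edges <- list()
  for (z in seq_len(d[1] - 1L)) {
    a <- lab[z, , ]; b <- lab[z + 1L, , ]
    # 26-connectivity: a voxel touches the 9 voxels around it on the next slice
    nr <- nrow(a); nc <- ncol(a)
    shifts <- list(
      cbind(as.vector(a), as.vector(b)),
      cbind(as.vector(a[-nr, ]), as.vector(b[-1, ])),
      cbind(as.vector(a[-1, ]), as.vector(b[-nr, ])),
      cbind(as.vector(a[, -nc]), as.vector(b[, -1])),
      cbind(as.vector(a[, -1]), as.vector(b[, -nc])),
      cbind(as.vector(a[-nr, -nc]), as.vector(b[-1, -1])),
      cbind(as.vector(a[-1, -1]), as.vector(b[-nr, -nc])),
      cbind(as.vector(a[-nr, -1]), as.vector(b[-1, -nc])),
      cbind(as.vector(a[-1, -nc]), as.vector(b[-nr, -1]))
    )
    for (s in shifts) {
      keep <- s[, 1] > 0L & s[, 2] > 0L
      if (any(keep)) edges[[length(edges) + 1L]] <- unique(s[keep, , drop = FALSE])
    }
  }
  if (length(edges) > 0L) {
    e <- unique(do.call(rbind, edges))
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(e))
    comp <- igraph::components(g)$membership
    comp <- as.integer(factor(comp))
    lab[lab > 0L] <- comp[lab[lab > 0L]]
  }
  lab
}

# 1D squared-distance transform (Felzenszwalb & Huttenlocher), f = input costs
.dt1d <- function(f, step) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); zi <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; zi[1] <- -Inf; zi[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + (q * step)^2) - (f[v[k]] + (v[k] * step)^2)) /
        (2 * q * step - 2 * v[k] * step)
      if (s <= zi[k]) { k <- k - 1L } else break
    }
    k <- k + 1L; v[k] <- q; zi[k] <- s; zi[k + 1L] <- Inf
  }
  k <- 1L
  d <- numeric(n)
  for (q in 1:n) {
    while (zi[k + 1L] < q * step) k <- k + 1L
    d[q] <- (q * step - v[k] * step)^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a 3D mask in physical units
#'
#' For each foreground voxel, the distance (nm) to the nearest background
#' voxel centre, computed separably along z, y, x with anisotropic spacing.
#'
#' @param mask logical 3D array (z, y, x).
#' @param spacingNm (sz, sy, sx) nm.
#' @return numeric 3D array of distances (0 outside the mask).
#' @export
distanceTransform3D <- function(mask, spacingNm) {
  d <- dim(mask)
  INF <- 1e18
  g <- array(ifelse(mask, INF, 0), d)
  for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    g[, y, x] <- .dt1d(g[, y, x], spacingNm[1])
  for (z in seq_len(d[1])) for (x in seq_len(d[3]))
    g[z, , x] <- .dt1d(g[z, , x], spacingNm[2])
  for (z in seq_len(d[1])) for (y in seq_len(d[2]))
    g[z, y, ] <- .dt1d(g[z, y, ], spacingNm[3])
  out <- sqrt(g)
  out[!mask] <- 0
  out
}

# deterministic per-stage child seed below 2^31
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 1e6
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
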