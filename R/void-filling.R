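#' @include AllClasses.R utils.R registration.R
NULL

#' Rasterize boundary points into a shell mask
#'
#' Each point is dilated by an L1 ball of radius `dilation` (radius 1 gives
#' the 7-voxel cross of a point and its 6 face neighbors), thickening the
#' predicted point cloud into a connected digital shell.
#'
#' @param points a [BoundaryPoints-class].
#' @param volumeShape integer(3) voxel dimensions.
#' @param dilation L1 dilation radius in voxels (0 = points only).
#' @param spacing,origin geometry of the returned mask.
#' @return a [CTMask-class] shell.
#' @export
voxelizePoints <- function(points, volumeShape, dilation = 1L,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is(points, "BoundaryPoints"))
  arr <- array(FALSE, volumeShape)
  arr[boundaryCoords(points)] <- TRUE
  if (dilation > 0L) arr <- dilate6(arr, as.integer(dilation))
  ctMask(arr * 1, spacing, origin)
}

## ---------------------------------------------------------------------------
## Octree decomposition (scan-conversion)
## ---------------------------------------------------------------------------

# 3D summed-volume table of a logical array, zero-padded at the low end so
# counts over [x0,x1]x[y0,y1]x[z0,z1] come from 8 lookups
summedVolumeTable <- function(S) {
  d <- dim(S)
  A <- array(0, d + 1L)
  A[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- S
  A <- apply(A, c(2, 3), cumsum)
  A <- aperm(apply(A, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(A, c(1, 2), cumsum), c(2, 3, 1))
}

# vectorized box counts: bounds are matrices of 1-based inclusive voxel
# ranges, already clipped to the volume
svtCount <- function(A, x0, x1, y0, y1, z0, z1) {
  A[cbind(x1 + 1L, y1 + 1L, z1 + 1L)] - A[cbind(x0, y1 + 1L, z1 + 1L)] -
  A[cbind(x1 + 1L, y0, z1 + 1L)] - A[cbind(x1 + 1L, y1 + 1L, z0)] +
  A[cbind(x0, y0, z1 + 1L)] + A[cbind(x0, y1 + 1L, z0)] +
  A[cbind(x1 + 1L, y0, z0)] - A[cbind(x0, y0, z0)]
}

#' Octree decomposition of a shell mask
#'
#' Scan-conversion subdivision of the volume's (power-of-two padded)
#' bounding cube: any node containing shell voxels is split until
#' `maxDepth`, so every intersection of the decomposition with the shell
#' lies on a finest leaf; homogeneous empty regions remain coarse leaves.
#'
#' @param shell a [CTMask-class] (or logical array) shell.
#' @param maxDepth subdivision depth; `NA` chooses the depth at which the
#'   finest leaves are single voxels.
#' @return an [Octree-class].
#' @export
octreeDecompose <- function(shell, maxDepth = NA) {
  S <- if (is(shell, "CTMask")) shell@data > 0.5 else shell > 0.5
  if (!any(S)) stop("shell is empty", call. = FALSE)
  d <- dim(S)
  L <- ceiling(log2(max(d)))
  if (is.na(maxDepth)) maxDepth <- L
  maxDepth <- as.integer(maxDepth)
  if (maxDepth < 1L) stop("maxDepth must be >= 1", call. = FALSE)
  rootSize <- 2L^max(L, maxDepth)
  A <- summedVolumeTable(S)
  countIn <- function(x0, y0, z0, size) {
    x1 <- pmin(x0 + size - 1L, d[1]); y1 <- pmin(y0 + size - 1L, d[2])
    z1 <- pmin(z0 + size - 1L, d[3])
    inb <- x0 <= d[1] & y0 <= d[2] & z0 <= d[3]
    out <- numeric(length(x0))
    if (any(inb))
      out[inb] <- svtCount(A, x0[inb], x1[inb], y0[inb], y1[inb], z0[inb],
                           z1[inb])
    out
  }
  ## level-wise subdivision, vectorized over nodes
  nodes <- data.frame(x0 = 1L, y0 = 1L, z0 = 1L, size = rootSize, depth = 0L)
  leaves <- list()
  while (nrow(nodes) > 0) {
    cnt <- countIn(nodes$x0, nodes$y0, nodes$z0, nodes$size[1])
    isLeaf <- cnt == 0 | nodes$depth >= maxDepth | nodes$size == 1L
    lf <- nodes[isLeaf, , drop = FALSE]
    if (nrow(lf) > 0) {
      lf$intersects <- cnt[isLeaf] > 0
      leaves[[length(leaves) + 1L]] <- lf
    }
    todo <- nodes[!isLeaf, , drop = FALSE]
    if (nrow(todo) == 0) break
    h <- todo$size[1] %/% 2L
    off <- expand.grid(dx = c(0L, 1L), dy = c(0L, 1L), dz = c(0L, 1L))
    kids <- do.call(rbind, lapply(seq_len(8L), function(i) {
      data.frame(x0 = todo$x0 + off$dx[i] * h, y0 = todo$y0 + off$dy[i] * h,
                 z0 = todo$z0 + off$dz[i] * h, size = h,
                 depth = todo$depth + 1L)
    }))
    nodes <- kids
  }
  leaves <- do.call(rbind, leaves)
  rownames(leaves) <- NULL
  new("Octree", leaves = leaves, maxDepth = maxDepth, dims = as.integer(d),
      rootSize = as.integer(rootSize))
}

## ---------------------------------------------------------------------------
## Parity labelling
## ---------------------------------------------------------------------------

# cumulative sum along one axis of a 3D array
cumsumAlong <- function(a, axis) {
  margins <- setdiff(1:3, axis)
  cum <- apply(a, margins, cumsum)   # dims in label order c(axis, margins)
  aperm(cum, order(c(axis, margins)))
}

reverseAlong <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# crossing parity along one axis direction: for each voxel, the number of
# completed shell runs strictly between the entry border and the voxel,
# modulo 2 (1 = inside). A maximal run of shell voxels counts as one
# crossing of the surface.
parityOneDirection <- function(S, axis, fromLow) {
  if (!fromLow) S <- reverseAlong(S, axis)
  ## run end along the axis: shell voxel whose successor is not shell
  nxt <- shift3d(S, axis, -1L, fill = FALSE)   # value at i+1
  runEnd <- S & !nxt
  cum <- cumsumAlong(runEnd, axis)
  before <- shift3d(cum, axis, 1L, fill = 0)   # completed runs strictly before
  par <- before %% 2
  if (!fromLow) par <- reverseAlong(par, axis)
  par
}

#' Inside/outside parity labels for a shell
#'
#' Labels every finest-leaf center (voxel) of the octree as outside (0) or
#' inside (1). Six border-anchored axis paths per voxel count crossings of
#' the shell's "intersecting edges" (a maximal run of shell voxels flips
#' the label once); a closed shell makes the six paths agree, and
#' disagreements — voids in the shell — are resolved by majority vote.
#' The exterior flood fill provides the consistency check: when the shell
#' is closed (the flood-fill enclosed region matches the parity interior)
#' the flood-fill labelling is used verbatim; when the shell is open the
#' flood leaks and the majority-vote parity fills the enclosed region.
#' Shell voxels are always labelled inside.
#'
#' @param octree the [Octree-class] built on the shell.
#' @param shell the shell [CTMask-class] (or logical array).
#' @return integer 0/1 array over the voxel grid with attributes
#'   `conflicts` (number of voxels whose six paths disagree) and `mode`
#'   ("closed" or "open").
#' @export
parityLabel <- function(octree, shell) {
  S <- if (is(shell, "CTMask")) shell@data > 0.5 else shell > 0.5
  if (!identical(dim(S), as.integer(octree@dims)) &&
      !identical(dim(S), octree@dims))
    stop("octree was not built on this shell", call. = FALSE)
  votes <- array(0, dim(S))
  for (axis in 1:3) for (fromLow in c(TRUE, FALSE))
    votes <- votes + parityOneDirection(S, axis, fromLow)
  conflicts <- sum(!S & votes > 0 & votes < 6)
  insideParity <- votes >= 3           # majority of 6 paths; tie -> inside
  floodOut <- floodFromBorder(!S)
  enclosed <- !S & !floodOut
  parityInterior <- insideParity & !S
  closed <- sum(enclosed) >= 0.5 * max(1L, sum(parityInterior))
  labels <- if (closed) S | enclosed else S | parityInterior | enclosed
  if (conflicts > 0)
    message("parityLabel: parity paths disagree at ", conflicts,
            " voxel(s); resolved by ",
            if (closed) "exterior flood fill (closed shell)"
            else "majority vote (open shell)")
  out <- array(as.integer(labels), dim(S))
  attr(out, "conflicts") <- conflicts
  attr(out, "mode") <- if (closed) "closed" else "open"
  out
}

## ---------------------------------------------------------------------------
## Dual contouring (surface-nets vertex placement)
## ---------------------------------------------------------------------------

#' Dual-contouring surface extraction from parity labels
#'
#' One mesh vertex per finest octree leaf cell crossed by the 0/1
#' interface, placed at the centroid of the cell's sign-change edge
#' crossings; quads (split into triangles) connect the four cells around
#' every sign-change edge, giving a watertight, consistently oriented
#' surface. Coarse homogeneous leaves contain no sign change by
#' construction and contribute nothing.
#'
#' @param octree the [Octree-class] built on the shell.
#' @param labels 0/1 array from [parityLabel()].
#' @param spacing,origin geometry used to place vertices in mm.
#' @return a [SurfaceMesh-class].
#' @export
dualContour <- function(octree, labels, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  occ <- labels > 0
  d <- dim(occ)
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  pd <- dim(P)
  ncell <- pd - 1L
  cellId <- function(cx, cy, cz)
    cx + (cy - 1) * ncell[1] + (cz - 1) * ncell[1] * ncell[2]

  ids <- list(); mids <- list(); quads <- list()
  for (axis in 1:3) {
    lowIdx <- lapply(pd, seq_len); lowIdx[[axis]] <- 1:(pd[axis] - 1L)
    hiIdx <- lapply(pd, seq_len); hiIdx[[axis]] <- 2:pd[axis]
    lowS <- P[lowIdx[[1]], lowIdx[[2]], lowIdx[[3]]]
    hiS <- P[hiIdx[[1]], hiIdx[[2]], hiIdx[[3]]]
    chg <- which(lowS != hiS)
    if (length(chg) == 0) next
    dd <- pd; dd[axis] <- pd[axis] - 1L
    e <- arrayInd(chg, dd)       # padded sample index of the low end
    insideLow <- lowS[chg]       # TRUE: inside at low end, normal along +axis
    i <- e[, 1]; j <- e[, 2]; k <- e[, 3]
    ## edge midpoint in voxel coordinates (padded sample p -> voxel p - 1)
    mid <- cbind(i - 1, j - 1, k - 1)
    mid[, axis] <- mid[, axis] + 0.5
    ## the four cells around the edge, ordered so A->B->C->D is CCW seen
    ## from the +axis side
    if (axis == 1L) {
      A <- cellId(i, j - 1, k - 1); B <- cellId(i, j, k - 1)
      C <- cellId(i, j, k);         D <- cellId(i, j - 1, k)
    } else if (axis == 2L) {
      A <- cellId(i - 1, j, k - 1); B <- cellId(i - 1, j, k)
      C <- cellId(i, j, k);         D <- cellId(i, j, k - 1)
    } else {
      A <- cellId(i - 1, j - 1, k); B <- cellId(i, j - 1, k)
      C <- cellId(i, j, k);         D <- cellId(i - 1, j, k)
    }
    quad <- cbind(A, B, C, D)
    flip <- !insideLow
    quad[flip, ] <- quad[flip, c(1, 4, 3, 2), drop = FALSE]
    ids[[axis]] <- c(A, B, C, D)
    mids[[axis]] <- rbind(mid, mid, mid, mid)
    quads[[axis]] <- quad
  }
  allIds <- unlist(ids)
  if (length(allIds) == 0) stop("no sign changes: nothing to contour",
                                call. = FALSE)
  allMid <- do.call(rbind, mids)
  acc <- rowsum(cbind(allMid, 1), allIds)
  cellKeys <- as.numeric(rownames(acc))
  verts <- acc[, 1:3, drop = FALSE] / acc[, 4]
  ## voxel -> physical mm
  verts <- sweep(sweep(verts - 1, 2, spacing, "*"), 2, origin, "+")
  dimnames(verts) <- NULL
  quadMat <- do.call(rbind, quads)
  qi <- matrix(match(quadMat, cellKeys), ncol = 4)
  faces <- rbind(qi[, c(1, 2, 3), drop = FALSE], qi[, c(1, 3, 4), drop = FALSE])
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = verts, faces = faces)
}

## ---------------------------------------------------------------------------
## Mesh utilities
## ---------------------------------------------------------------------------

meshEdgeKeys <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Watertightness, Euler characteristic, volume, components
#'
#' `isWatertight` checks that every undirected edge is shared by exactly
#' two triangles; `eulerCharacteristic` returns V - E + F (2 for a
#' genus-0 closed surface); `meshVolume` integrates the divergence theorem
#' over the oriented triangles (mm^3); `meshComponents` counts connected
#' components of the vertex graph.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return logical / integer / numeric as appropriate.
#' @export
isWatertight <- function(mesh) {
  if (nrow(mesh@faces) == 0) return(FALSE)
  all(table(meshEdgeKeys(mesh)) == 2L)
}

#' @rdname isWatertight
#' @export
eulerCharacteristic <- function(mesh) {
  V <- length(unique(as.vector(mesh@faces)))
  E <- length(unique(meshEdgeKeys(mesh)))
  F <- nrow(mesh@faces)
  V - E + F
}

#' @rdname isWatertight
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ## scalar triple product a . (b x c) / 6
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' @rdname isWatertight
#' @export
meshComponents <- function(mesh) {
  n <- nrow(mesh@vertices)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  f <- mesh@faces
  for (i in seq_len(nrow(f))) {
    a <- find(f[i, 1]); b <- find(f[i, 2]); c_ <- find(f[i, 3])
    parent[b] <- a; parent[find(c_)] <- find(a)
  }
  length(unique(vapply(unique(as.vector(f)), find, integer(1))))
}

# Repair 2x2 diagonal (checkerboard) configurations in every axis-aligned
# plane by adding solid voxels until none remain ("well-composed" image).
# A checkerboard plaquette would put four sign-change edges on one cell
# face, making the dual-contoured surface non-manifold; adding one voxel of
# the empty diagonal removes it. Monotone, hence terminating.
makeWellComposed <- function(solid, maxIter = 50L) {
  d <- dim(solid)
  for (it in seq_len(maxIter)) {
    added <- FALSE
    for (axes in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      a1 <- axes[1]; a2 <- axes[2]
      idx <- lapply(d, seq_len)
      lo1 <- idx; lo1[[a1]] <- 1:(d[a1] - 1L)
      hi1 <- idx; hi1[[a1]] <- 2:d[a1]
      sub <- function(s, i1, i2) {
        j <- idx; j[[a1]] <- i1[[a1]]; j[[a2]] <- i2[[a2]]
        s[j[[1]], j[[2]], j[[3]]]
      }
      lo2 <- idx; lo2[[a2]] <- 1:(d[a2] - 1L)
      hi2 <- idx; hi2[[a2]] <- 2:d[a2]
      s00 <- sub(solid, lo1, lo2); s10 <- sub(solid, hi1, lo2)
      s01 <- sub(solid, lo1, hi2); s11 <- sub(solid, hi1, hi2)
      chk <- (s00 & s11 & !s10 & !s01) | (!s00 & !s11 & s10 & s01)
      if (any(chk)) {
        added <- TRUE
        w <- which(chk, arr.ind = TRUE)
        ## fill the low corner of the empty diagonal
        fill <- w
        firstEmptyLow <- !s00[chk]          # s00 empty -> fill (lo1, lo2)
        fill[!firstEmptyLow, a1] <- fill[!firstEmptyLow, a1] + 1L
        solid[fill] <- TRUE
      }
    }
    if (!added) return(solid)
  }
  solid
}

## ---------------------------------------------------------------------------
## Composite void filling
## ---------------------------------------------------------------------------

#' Repair a boundary point cloud into a closed surface and solid mask
#'
#' The five-step repair: rasterize the points into a dilated shell, build
#' the scan-conversion octree, parity-label inside/outside (majority vote
#' across border-anchored paths resolves voids), dual-contour the 0/1
#' interface, and return the watertight mesh together with the solid mask
#' of voxels inside it. The solid is cavity-free (an exterior flood fill
#' reaches every background voxel) and, by default, restricted to its
#' largest connected component.
#'
#' @param points a [BoundaryPoints-class] (at least 4 non-coplanar points).
#' @param volumeShape integer(3) voxel dimensions.
#' @param spacing,origin grid geometry (mm).
#' @param dilation shell dilation radius (L1 ball).
#' @param maxDepth octree depth (NA = single-voxel finest leaves).
#' @param keepLargest keep only the largest connected solid component.
#' @param smoothWidth odd window (voxels) for surface regularization: the
#'   solid indicator is box-blurred and re-thresholded at 0.5, which
#'   suppresses the voxel-scale raggedness a noisy boundary point cloud
#'   induces while leaving an already-smooth solid essentially unchanged.
#'   Use 0 or 1 to disable.
#' @return list with `mesh` ([SurfaceMesh-class]) and `mask`
#'   ([CTMask-class]).
#' @export
fillVoids <- function(points, volumeShape, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), dilation = 1L, maxDepth = NA,
                      keepLargest = TRUE, smoothWidth = 7L) {
  stopifnot(is(points, "BoundaryPoints"))
  pts <- boundaryCoords(points)
  if (nrow(pts) < 4L) stop("need at least 4 points", call. = FALSE)
  ctr <- scale(pts, scale = FALSE)
  if (qr(ctr)$rank < 3L)
    stop("degenerate (coplanar) point cloud", call. = FALSE)
  shell <- voxelizePoints(points, volumeShape, dilation, spacing, origin)
  octree <- octreeDecompose(shell)
  labels <- parityLabel(octree, shell)
  solid <- labels > 0
  ## cavity removal: any non-solid region not reachable from the border is
  ## an interior cavity and becomes solid
  solid <- !floodFromBorder(!solid)
  if (smoothWidth >= 3L) {
    solid <- boxBlur3d(solid * 1, as.integer(smoothWidth)) > 0.5
    solid <- !floodFromBorder(!solid)
  }
  ## the dilation thickened the shell symmetrically; erode the solid back by
  ## the same radius so the surface passes through the input points rather
  ## than the outer face of the dilated shell
  if (dilation > 0L) {
    eroded <- erode6(solid, as.integer(dilation))
    if (any(eroded)) solid <- eroded
    solid <- !floodFromBorder(!solid)   # re-assert cavity-freeness
  }
  if (keepLargest) {
    lab <- labelComponents(solid)
    sizes <- attr(lab, "sizes")
    if (length(sizes) > 1L) solid <- lab == which.max(sizes)
  }
  solid <- makeWellComposed(solid)
  solid <- !floodFromBorder(!solid)
  mesh <- dualContour(octree, array(as.integer(solid), volumeShape),
                      spacing, origin)
  if (meshVolume(mesh) < 0)
    mesh <- new("SurfaceMesh", vertices = mesh@vertices,
                faces = mesh@faces[, c(1, 3, 2), drop = FALSE])
  list(mesh = mesh, mask = ctMask(solid * 1, spacing, origin))
}

#' Remove boundary points far from the repaired surface
#'
#' Keeps only points within `delta` mm of the mesh surface (measured to the
#' mesh vertices, which sample the surface at voxel resolution). This is
#' the redundant-point elimination step: stray detections that survive into
#' the point cloud but are not supported by the reconstructed surface are
#' discarded.
#'
#' @param points a [BoundaryPoints-class].
#' @param mesh a watertight [SurfaceMesh-class].
#' @param delta mm tolerance.
#' @param spacing,origin grid geometry mapping voxel points to mm.
#' @return a filtered [BoundaryPoints-class] (possibly smaller, never
#'   larger).
#' @export
pruneRedundantPoints <- function(points, mesh, delta, spacing = c(1, 1, 1),
                                 origin = c(0, 0, 0)) {
  stopifnot(is(points, "BoundaryPoints"))
  if (!isWatertight(mesh)) stop("mesh must be watertight", call. = FALSE)
  P <- sweep(sweep(boundaryCoords(points) - 1, 2, spacing, "*"), 2, origin,
             "+")
  dmin <- minCrossDist(P, mesh@vertices)
  keep <- dmin <= delta
  if (!any(keep)) stop("pruning removed every point", call. = FALSE)
  boundaryPoints(boundaryCoords(points)[keep, , drop = FALSE],
                 source = points@source)
}

## ---------------------------------------------------------------------------
## Mesh export
## ---------------------------------------------------------------------------

#' Write a mesh as ASCII STL or PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeMeshSTL <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
  n <- n / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  tri <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
    c_[, 1], c_[, 2], c_[, 3])
  writeLines(tri, con)
  writeLines("endsolid surface", con)
  invisible(path)
}

#' @rdname writeMeshSTL
#' @export
writeMeshPLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
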