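#' @include AllClasses.R
NULL

#' Construct a CTVolume
#'
#' @param data 3D numeric array.
#' @param spacing mm per voxel, numeric(3).
#' @param origin mm position of voxel (1,1,1).
#' @return a [CTVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(4, 4, 4)))
#' dim(v)
#' @export
ctVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a CTMask
#'
#' @param data 3D array with values in \{0, 1\} (logical accepted).
#' @inheritParams ctVolume
#' @return a [CTMask-class].
#' @export
ctMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("CTMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LandmarkSet
#'
#' @param moving,fixed n x 3 matrices of paired mm coordinates.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(moving, fixed) {
  new("LandmarkSet", moving = as.matrix(moving), fixed = as.matrix(fixed))
}

#' Construct a BoundaryPoints set
#'
#' @param points n x 3 integer voxel coordinates (1-based).
#' @param source "prior" or "predicted".
#' @return a [BoundaryPoints-class].
#' @export
boundaryPoints <- function(points, source = "prior") {
  p <- as.matrix(points)
  storage.mode(p) <- "integer"
  dimnames(p) <- NULL
  new("BoundaryPoints", points = p, source = source)
}

#' Voxel/physical coordinate conversion
#'
#' `voxelToPhys` maps 1-based (possibly fractional) voxel indices to mm;
#' `physToVoxel` is its exact inverse.
#'
#' @param coords n x 3 matrix of coordinates.
#' @param geom a [CTVolume-class], [CTMask-class] or
#'   [DeformationField-class] carrying spacing/origin.
#' @return n x 3 matrix in the other coordinate system.
#' @export
voxelToPhys <- function(coords, geom) {
  coords <- rbindMatrix(coords)
  sweep(sweep(coords - 1, 2, spacing(geom), "*"), 2, origin(geom), "+")
}

#' @rdname voxelToPhys
#' @export
physToVoxel <- function(coords, geom) {
  coords <- rbindMatrix(coords)
  sweep(sweep(coords, 2, origin(geom), "-"), 2, spacing(geom), "/") + 1
}

# coerce a bare numeric(3) to a 1 x 3 matrix
rbindMatrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

## ---------------------------------------------------------------------------
## internal array helpers
## ---------------------------------------------------------------------------

# shift a 3D array by one voxel along `axis` (+1 or -1 step), filling with
# `fill`; used for 6-neighborhood morphology
shift3d <- function(a, axis, step, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (step == 1L) {       # neighbor at index - 1
    dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1)
  } else {
    dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# logical OR over the 6 face neighbors (out-of-bounds treated as `fill`)
neighborAny <- function(a, fill = FALSE) {
  r <- array(FALSE, dim(a))
  for (axis in 1:3) for (s in c(1L, -1L))
    r <- r | shift3d(a, axis, s, fill = fill)
  r
}

dilate6 <- function(mask, times = 1L) {
  m <- mask
  for (i in seq_len(times)) m <- m | neighborAny(m, fill = FALSE)
  m
}

erode6 <- function(mask, times = 1L) {
  m <- mask
  for (i in seq_len(times)) m <- m & !neighborAny(!m, fill = TRUE)
  m
}

# linear index <-> (x, y, z) for dim d
linIndex <- function(x, y, z, d) {
  as.integer(x + (y - 1L) * d[1] + (z - 1L) * as.double(d[1]) * d[2])
}

# flood fill from the volume border through `open` voxels (logical array);
# returns logical array of reachable voxels. 6-connectivity, frontier BFS.
floodFromBorder <- function(open) {
  d <- dim(open)
  n <- prod(d)
  reach <- logical(n)
  openv <- as.logical(open)
  # seed: all open voxels on any face of the volume
  idx <- array(seq_len(n), d)
  seeds <- unique(c(idx[c(1, d[1]), , ], idx[, c(1, d[2]), ], idx[, , c(1, d[3])]))
  seeds <- seeds[openv[seeds]]
  reach[seeds] <- TRUE
  frontier <- seeds
  nx <- d[1]; nxy <- d[1] * d[2]
  while (length(frontier)) {
    f <- frontier
    x <- ((f - 1L) %% nx) + 1L
    y <- (((f - 1L) %/% nx) %% d[2]) + 1L
    z <- ((f - 1L) %/% nxy) + 1L
    nb <- c(f[x > 1L] - 1L, f[x < d[1]] + 1L,
            f[y > 1L] - nx, f[y < d[2]] + nx,
            f[z > 1L] - nxy, f[z < d[3]] + nxy)
    nb <- unique(nb[openv[nb] & !reach[nb]])
    reach[nb] <- TRUE
    frontier <- nb
  }
  array(reach, d)
}

# label 6-connected components of a logical array; returns integer array
# (0 = background) and component sizes as attribute "sizes"
labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  maskv <- as.logical(mask)
  labv <- integer(prod(d))
  remaining <- which(maskv)
  nx <- d[1]; nxy <- d[1] * d[2]
  comp <- 0L
  sizes <- integer(0)
  seen <- logical(prod(d))
  for (start in remaining) {
    if (seen[start]) next
    comp <- comp + 1L
    frontier <- start
    seen[start] <- TRUE
    labv[start] <- comp
    count <- 1L
    while (length(frontier)) {
      f <- frontier
      x <- ((f - 1L) %% nx) + 1L
      y <- (((f - 1L) %/% nx) %% d[2]) + 1L
      z <- ((f - 1L) %/% nxy) + 1L
      nb <- c(f[x > 1L] - 1L, f[x < d[1]] + 1L,
              f[y > 1L] - nx, f[y < d[2]] + nx,
              f[z > 1L] - nxy, f[z < d[3]] + nxy)
      nb <- unique(nb[maskv[nb] & !seen[nb]])
      seen[nb] <- TRUE
      labv[nb] <- comp
      count <- count + length(nb)
      frontier <- nb
    }
    sizes <- c(sizes, count)
  }
  lab <- array(labv, d)
  attr(lab, "sizes") <- sizes
  lab
}

# trilinear interpolation of 3D array `a` at fractional 1-based voxel
# coordinates (n x 3); outside values are `fill`
interpTrilinear <- function(a, coords, fill = 0) {
  d <- dim(a)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(fill, length(x))
  ok <- x0 >= 1 & y0 >= 1 & z0 >= 1 & x0 <= d[1] & y0 <= d[2] & z0 <= d[3] &
        (x0 + (fx > 0)) <= d[1] & (y0 + (fy > 0)) <= d[2] & (z0 + (fz > 0)) <= d[3]
  if (!any(ok)) return(out)
  x0 <- as.integer(x0[ok]); y0 <- as.integer(y0[ok]); z0 <- as.integer(z0[ok])
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  g <- function(xi, yi, zi) a[cbind(xi, yi, zi)]
  v <- g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       g(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
       g(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
       g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
       g(x1, y1, z0) * fx * fy * (1 - fz) +
       g(x1, y0, z1) * fx * (1 - fy) * fz +
       g(x0, y1, z1) * (1 - fx) * fy * fz +
       g(x1, y1, z1) * fx * fy * fz
  out[ok] <- v
  out
}

# nearest-neighbor interpolation (preserves the value set)
interpNearest <- function(a, coords, fill = 0) {
  d <- dim(a)
  xi <- round(coords[, 1]); yi <- round(coords[, 2]); zi <- round(coords[, 3])
  out <- rep(fill, nrow(coords))
  ok <- xi >= 1 & yi >= 1 & zi >= 1 & xi <= d[1] & yi <= d[2] & zi <= d[3]
  out[ok] <- a[cbind(as.integer(xi[ok]), as.integer(yi[ok]), as.integer(zi[ok]))]
  out
}

# for each row of P (n x 3, mm), the minimum Euclidean distance to any row
# of Q; chunked so the cross-distance matrix stays small
minCrossDist <- function(P, Q, chunk = 1024L) {
  n <- nrow(P)
  q2 <- rowSums(Q^2)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Pi <- P[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Pi^2), q2, "+") - 2 * tcrossprod(Pi, Q)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

# separable box-mean blur of a 3D numeric array (window w, odd), computed
# with running sums along each axis; windows are clipped at the borders
boxBlur3d <- function(a, w) {
  h <- (w - 1L) %/% 2L
  if (h < 1L) return(a)
  for (ax in 1:3) {
    dn <- dim(a)[ax]
    cum <- cumsumAlong(a, ax)
    slice <- function(A, i) {
      j <- lapply(dim(A), seq_len); j[[ax]] <- i
      A[j[[1]], j[[2]], j[[3]]]
    }
    hi <- slice(cum, pmin(seq_len(dn) + h, dn))
    loI <- seq_len(dn) - h - 1L
    lo <- slice(cum, pmax(loI, 1L))
    zero <- which(loI < 1L)
    j <- lapply(dim(a), seq_len); j[[ax]] <- zero
    lo[j[[1]], j[[2]], j[[3]]] <- 0
    cnt <- pmin(seq_len(dn) + h, dn) - pmax(seq_len(dn) - h, 1L) + 1L
    a <- sweep(hi - lo, ax, cnt, "/")
  }
  a
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopIfNot3d <- function(x, what = "volume") {
  if (!is(x, "CTVolume")) stop(what, " must be a CTVolume/CTMask", call. = FALSE)
  invisible(TRUE)
}

sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    max(abs(spacing(a) - spacing(b))) < tol &&
    max(abs(origin(a) - origin(b))) < tol
}
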