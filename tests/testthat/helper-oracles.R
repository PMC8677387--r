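# Independent oracles and small geometric fixtures used across the suite.

# digital ball mask (array of 0/1) centered at ctr with radius r (voxels)
makeBallArray <- function(d, ctr, r) {
  ii <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  arr <- array(0, d)
  arr[ii[rowSums(sweep(ii, 2, ctr)^2) <= r^2, , drop = FALSE]] <- 1
  arr
}

makeCubeArray <- function(d, lo, hi) {
  arr <- array(0, d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  arr
}

# brute-force 6-neighborhood surface voxels of a 0/1 array
bruteSurface <- function(a) {
  d <- dim(a)
  fg <- which(a == 1, arr.ind = TRUE)
  keep <- apply(fg, 1, function(p) {
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[axis] <- q[axis] + s
      if (any(q < 1) || any(q > d)) return(TRUE)
      if (a[q[1], q[2], q[3]] == 0) return(TRUE)
    }
    FALSE
  })
  fg[keep, , drop = FALSE]
}

# O(n^2) pairwise surface-distance oracle for the five metrics (voxel
# coordinates scaled by spacing)
bruteMetrics <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- sweep(bruteSurface(a) - 1, 2, spacing, "*")
  sb <- sweep(bruteSurface(b) - 1, 2, spacing, "*")
  dAB <- apply(sa, 1, function(p) sqrt(min(colSums((t(sb) - p)^2))))
  dBA <- apply(sb, 1, function(p) sqrt(min(colSums((t(sa) - p)^2))))
  n <- length(dAB) + length(dBA)
  nA <- sum(a); nB <- sum(b)
  c(voe = 100 * (1 - sum(a & b) / sum(a | b)),
    rvd = 100 * (nA - nB) / nB,
    assd = (sum(dAB) + sum(dBA)) / n,
    rmsssd = sqrt((sum(dAB^2) + sum(dBA^2)) / n),
    mssd = max(dAB, dBA))
}

# exhaustive least-squares sparse-coding oracle: minimum residual over all
# supports of size <= T0
bruteOmpResidual <- function(D, y, T0) {
  t <- ncol(D)
  best <- sqrt(sum(y^2))
  for (k in seq_len(T0)) {
    for (s in utils::combn(t, k, simplify = FALSE)) {
      Ds <- D[, s, drop = FALSE]
      r <- y - Ds %*% qr.coef(qr(Ds), y)
      best <- min(best, sqrt(sum(r^2)))
    }
  }
  best
}

# exterior flood fill oracle (6-connectivity) on a 0/1 shell: TRUE where a
# voxel is reachable from the border without entering the shell
bruteExteriorFill <- function(shell) {
  d <- dim(shell)
  open <- shell == 0
  reach <- array(FALSE, d)
  q <- list()
  for (x in c(1, d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    if (open[x, y, z]) q[[length(q) + 1]] <- c(x, y, z)
  for (y in c(1, d[2])) for (x in seq_len(d[1])) for (z in seq_len(d[3]))
    if (open[x, y, z]) q[[length(q) + 1]] <- c(x, y, z)
  for (z in c(1, d[3])) for (x in seq_len(d[1])) for (y in seq_len(d[2]))
    if (open[x, y, z]) q[[length(q) + 1]] <- c(x, y, z)
  for (p in q) reach[p[1], p[2], p[3]] <- TRUE
  repeat {
    grew <- FALSE
    idx <- which(reach, arr.ind = TRUE)
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, axis] <- nb[, axis] + s
      ok <- nb[, axis] >= 1 & nb[, axis] <= d[axis]
      nb <- nb[ok, , drop = FALSE]
      new <- nb[open[nb] & !reach[nb], , drop = FALSE]
      if (nrow(new) > 0) { reach[new] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  reach
}

# small, fast phantom for module-level tests
smallPhantomSpec <- function(seed = 1L, deformAmplitude = 3) {
  phantomSpec(shape = c(64L, 64L, 64L), organRadii = c(18, 16, 15),
              deformAmplitude = deformAmplitude, seed = seed)
}

voeOf <- function(a, b) {
  A <- (if (is(a, "CTMask")) imgData(a) else a) > 0.5
  B <- (if (is(b, "CTMask")) imgData(b) else b) > 0.5
  100 * (1 - sum(A & B) / sum(A | B))
}
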