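#' @include AllClasses.R utils.R gabor.R sparse-dictionary.R registration.R
NULL

#' Sample training patches on the gold-standard boundary
#'
#' Draws `N` centers uniformly without replacement from the 6-neighborhood
#' surface voxels of the gold mask (restricted to those whose patch lies
#' fully inside the volume) and computes their Gabor features on the
#' training volume.
#'
#' @param volume the training [CTVolume-class].
#' @param goldMask its gold-standard [CTMask-class].
#' @param patchSize odd integer(2).
#' @param N number of patches.
#' @param seed integer seed for the draw.
#' @param bank a [GaborBank-class].
#' @param normalizeFeatures scale every feature column to unit L2 norm, so
#'   dictionary reconstruction error measures texture-pattern similarity
#'   rather than texture energy (without it, low-energy flat patches score
#'   spuriously small errors). Must match the setting used at selection
#'   time.
#' @return a [PatchSet-class] (the training matrix Y).
#' @export
sampleTrainingPatches <- function(volume, goldMask, patchSize, N, seed,
                                  bank = buildGaborBank(),
                                  normalizeFeatures = TRUE) {
  stopIfNot3d(volume)
  stopifnot(is(goldMask, "CTMask"))
  if (!identical(dim(volume), dim(goldMask)))
    stop("volume and gold mask must share a grid", call. = FALSE)
  patchSize <- as.integer(rep(patchSize, length.out = 2))
  surf <- boundaryCoords(extractSurfacePoints(goldMask))
  ok <- checkPatchInside(surf, dim(volume), patchSize)
  eligible <- surf[ok, , drop = FALSE]
  if (nrow(eligible) < N)
    stop("only ", nrow(eligible), " eligible boundary centers for N = ", N,
         call. = FALSE)
  pick <- withSeed(seed, sample(nrow(eligible), N))
  ps <- patchMatrix(volume, eligible[pick, , drop = FALSE], patchSize, bank)
  if (normalizeFeatures) {
    f <- normalizeColumns(ps@features)
    ps <- new("PatchSet", features = f, centers = ps@centers,
              patchSize = ps@patchSize)
  }
  ps
}

# unit-L2 columns; zero columns are left as zero
normalizeColumns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm < 1e-12] <- 1
  sweep(M, 2, nrm, "/")
}

#' Axis-neighborhood candidate centers around the prior boundary
#'
#' For each prior-boundary vertex v the candidates are `v +- k * e_axis`
#' for `k = 1..radius` along x, y and z, clipped to the volume bounds. The
#' default radius 5 yields up to 30 candidates per vertex (10 per axis).
#'
#' @param priorBoundary a [BoundaryPoints-class] (the warped gold surface).
#' @param radius neighborhood radius in voxels (>= 1).
#' @param volumeShape integer(3) voxel dimensions.
#' @return a [CandidateSet-class].
#' @examples
#' b <- boundaryPoints(matrix(c(10, 10, 10), 1))
#' cs <- candidateCenters(b, 5, c(20, 20, 20))
#' nrow(cs@candidates)  # 30
#' @export
candidateCenters <- function(priorBoundary, radius = 5L, volumeShape) {
  stopifnot(is(priorBoundary, "BoundaryPoints"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  V <- boundaryCoords(priorBoundary)
  if (nrow(V) == 0L) stop("empty prior boundary", call. = FALSE)
  offs <- c(seq_len(radius), -seq_len(radius))
  nOff <- length(offs)
  nV <- nrow(V)
  ## one block per axis: each vertex replicated for every offset
  cand <- vector("list", 3L)
  vid <- rep(rep(seq_len(nV), each = nOff), times = 3L)
  for (axis in 1:3) {
    block <- V[rep(seq_len(nV), each = nOff), , drop = FALSE]
    block[, axis] <- block[, axis] + rep(offs, times = nV)
    cand[[axis]] <- block
  }
  cand <- do.call(rbind, cand)
  inb <- cand[, 1] >= 1L & cand[, 1] <= volumeShape[1] &
         cand[, 2] >= 1L & cand[, 2] <= volumeShape[2] &
         cand[, 3] >= 1L & cand[, 3] <= volumeShape[3]
  new("CandidateSet", candidates = cand[inb, , drop = FALSE],
      vertex = as.integer(vid[inb]), vertices = V, radius = radius)
}

#' Select predicted boundary points by minimum reconstruction error
#'
#' For every prior-boundary vertex, each of its candidate patches is scored
#' by the OMP reconstruction error under the trained dictionary, and the
#' candidate with the smallest error becomes that vertex's predicted
#' boundary point. Errors equal within 1e-12 are ties, broken by the lowest
#' (z, y, x)-lexicographic center. Candidates whose patch crosses the
#' volume border are dropped (counted in a message); a vertex left with no
#' evaluable candidate is skipped. The returned points are deduplicated.
#'
#' @param cands a [CandidateSet-class].
#' @param volume the target [CTVolume-class].
#' @param patchSize odd integer(2).
#' @param D a trained [GaborDictionary-class].
#' @param T0 sparsity bound used for scoring.
#' @param bank the [GaborBank-class] used for features.
#' @param featureStack optional precomputed [gaborFeatureStack()] for
#'   `volume` (avoids re-filtering).
#' @param normalizeFeatures scale candidate feature columns to unit L2 norm
#'   before scoring; must match how the dictionary was trained (see
#'   [sampleTrainingPatches()]).
#' @param errorThreshold optional: instead of the strict per-vertex argmin,
#'   also keep every candidate whose error is below this value.
#' @return a [BoundaryPoints-class] with `source = "predicted"`.
#' @export
selectBoundaryPoints <- function(cands, volume, patchSize, D, T0,
                                 bank = buildGaborBank(),
                                 featureStack = NULL,
                                 normalizeFeatures = TRUE,
                                 errorThreshold = NULL) {
  stopifnot(is(cands, "CandidateSet"), is(D, "GaborDictionary"))
  stopIfNot3d(volume)
  patchSize <- as.integer(rep(patchSize, length.out = 2))
  C <- cands@candidates
  vid <- cands@vertex
  keep <- checkPatchInside(C, dim(volume), patchSize)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message("selectBoundaryPoints: dropped ", nDropped,
            " border-crossing candidate(s)")
  C <- C[keep, , drop = FALSE]
  vid <- vid[keep]
  if (nrow(C) == 0L) stop("no evaluable candidates", call. = FALSE)

  ## score unique candidate voxels once
  key <- paste(C[, 1], C[, 2], C[, 3])
  uniq <- !duplicated(key)
  U <- C[uniq, , drop = FALSE]
  if (is.null(featureStack)) {
    feats <- patchMatrix(volume, U, patchSize, bank)@features
  } else {
    feats <- stackFeatures(featureStack, U)
  }
  if (normalizeFeatures) feats <- normalizeColumns(feats)
  errU <- reconstructionErrors(D, feats, T0)
  err <- errU[match(key, key[uniq])]

  ## per-vertex argmin with documented tie-break
  ord <- order(vid, err, C[, 3], C[, 2], C[, 1])
  vidO <- vid[ord]; errO <- err[ord]; CO <- C[ord, , drop = FALSE]
  firstOfVertex <- !duplicated(vidO)
  ## ties: among candidates of a vertex with error within 1e-12 of its
  ## minimum, the (z, y, x) order above already puts the winner first
  minErr <- errO[firstOfVertex][match(vidO, vidO[firstOfVertex])]
  tieSet <- errO <= minErr + 1e-12
  ordTie <- order(vidO[tieSet], CO[tieSet, 3], CO[tieSet, 2], CO[tieSet, 1])
  vT <- vidO[tieSet][ordTie]; CT <- CO[tieSet, , drop = FALSE][ordTie, , drop = FALSE]
  sel <- CT[!duplicated(vT), , drop = FALSE]

  if (!is.null(errorThreshold)) {
    extra <- C[err <= errorThreshold, , drop = FALSE]
    sel <- rbind(sel, extra)
  }
  sel <- sel[!duplicated(paste(sel[, 1], sel[, 2], sel[, 3])), , drop = FALSE]
  nSkipped <- nrow(cands@vertices) - length(unique(vid))
  if (nSkipped > 0)
    message("selectBoundaryPoints: ", nSkipped,
            " vertex(es) had no evaluable candidate")
  boundaryPoints(sel, source = "predicted")
}

#' Export boundary points as CSV or as a shell mask
#'
#' @param points a [BoundaryPoints-class].
#' @param path destination CSV (columns x, y, z; 1-based voxel indices).
#' @return invisibly, `path`.
#' @export
writeBoundaryCSV <- function(points, path) {
  df <- as.data.frame(boundaryCoords(points))
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBoundaryCSV
#' @param volumeShape integer(3) voxel dimensions of the target grid.
#' @param spacing,origin geometry for the returned mask.
#' @return `boundaryMask`: a [CTMask-class] with 1 at each point.
#' @export
boundaryMask <- function(points, volumeShape, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  arr <- array(0, volumeShape)
  arr[boundaryCoords(points)] <- 1
  ctMask(arr, spacing, origin)
}
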