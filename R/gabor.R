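#' @include AllClasses.R utils.R
NULL

#' Specify a Gabor filter bank
#'
#' The default bank has 6 orientations (every 30 degrees in [0, 180)) at 4
#' scales, so patch features are 24-dimensional — the feature length the
#' dictionary's row dimension is built on. Orientations, scales and
#' wavelengths are all configurable; the feature length is always
#' `nOrientations * nScales`.
#'
#' @param nOrientations number of orientations, evenly spaced in [0, pi).
#' @param wavelengths voxels per cycle, strictly increasing, one per scale.
#' @param sigmaFactor Gaussian envelope sigma as a fraction of wavelength.
#' @param kernelRadius kernel half-width in voxels; the kernel must support
#'   at least one full cycle of the largest wavelength.
#' @return a list spec consumed by [buildGaborBank()].
#' @export
gaborBankSpec <- function(nOrientations = 6L, wavelengths = c(3, 4, 6, 8),
                          sigmaFactor = 0.56, kernelRadius = 6L) {
  if (nOrientations < 1L) stop("nOrientations must be >= 1", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (2L * kernelRadius + 1L < max(wavelengths))
    stop("kernelRadius too small: kernel must support one full cycle of the ",
         "largest wavelength (", max(wavelengths), " voxels)", call. = FALSE)
  list(nOrientations = as.integer(nOrientations),
       wavelengths = as.numeric(wavelengths),
       sigmaFactor = as.numeric(sigmaFactor),
       kernelRadius = as.integer(kernelRadius))
}

#' Build the Gabor kernel bank
#'
#' Real even-symmetric (cosine-phase) 2D Gabor kernels, one per
#' (orientation, scale) pair, each DC-corrected to exactly zero mean and
#' scaled to unit L2 norm. Ordering is scale-major:
#' kernel `j` has orientation `(j - 1) %% nOrientations + 1` and scale
#' `(j - 1) %/% nOrientations + 1`.
#'
#' @param spec output of [gaborBankSpec()].
#' @return a [GaborBank-class].
#' @examples
#' bank <- buildGaborBank(gaborBankSpec())
#' length(bank@kernels)  # 24
#' @export
buildGaborBank <- function(spec = gaborBankSpec()) {
  r <- spec$kernelRadius
  xs <- -r:r
  grid <- expand.grid(x = xs, y = xs)
  thetas <- (seq_len(spec$nOrientations) - 1) * pi / spec$nOrientations
  kernels <- vector("list", spec$nOrientations * length(spec$wavelengths))
  j <- 0L
  for (lambda in spec$wavelengths) {
    sigma <- spec$sigmaFactor * lambda
    for (theta in thetas) {
      j <- j + 1L
      xr <- grid$x * cos(theta) + grid$y * sin(theta)
      yr <- -grid$x * sin(theta) + grid$y * cos(theta)
      k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
      k <- k - mean(k)              # DC correction
      k <- k / sqrt(sum(k^2))       # unit L2 norm
      kernels[[j]] <- matrix(k, 2L * r + 1L, 2L * r + 1L)
    }
  }
  new("GaborBank", kernels = kernels,
      orientations = thetas, wavelengths = spec$wavelengths,
      sigmaFactor = spec$sigmaFactor, kernelRadius = r)
}

# feature length of a bank
bankSize <- function(bank) length(bank@kernels)

# filter one axial slice with every kernel; returns (nx, ny, m) array of
# raw (signed) responses. Replicate boundary keeps border behavior defined.
filterSlice <- function(slice, bank) {
  m <- bankSize(bank)
  out <- array(0, c(dim(slice), m))
  for (j in seq_len(m))
    out[, , j] <- EBImage::filter2(slice, bank@kernels[[j]],
                                   boundary = "replicate")
  out
}

# mean |response| over the (px, py) window centered at each pixel, for one
# already-filtered slice channel; a box filter, exact for interior windows
boxMean <- function(img, patchSize) {
  box <- matrix(1 / prod(patchSize), patchSize[1], patchSize[2])
  EBImage::filter2(img, box, boundary = "replicate")
}

checkPatchInside <- function(centers, d, patchSize) {
  hx <- (patchSize[1] - 1L) %/% 2L
  hy <- (patchSize[2] - 1L) %/% 2L
  centers[, 1] - hx >= 1L & centers[, 1] + hx <= d[1] &
  centers[, 2] - hy >= 1L & centers[, 2] + hy <= d[2] &
  centers[, 3] >= 1L & centers[, 3] <= d[3]
}

#' Gabor feature vector of one patch
#'
#' Entry j is the mean over the in-plane patch (axial slice through the
#' center) of the absolute response of kernel j. Because the kernels are
#' zero-mean, a constant-intensity patch maps to the zero vector, and the
#' feature is invariant to adding a constant to the image.
#'
#' @param volume a [CTVolume-class].
#' @param center voxel coordinate (1-based, length 3).
#' @param patchSize odd integer(2), in-plane patch extent.
#' @param bank a [GaborBank-class].
#' @return numeric feature vector of length `nOrientations * nScales`.
#' @export
patchFeature <- function(volume, center, patchSize, bank) {
  stopIfNot3d(volume)
  center <- matrix(as.integer(center), ncol = 3)
  patchSize <- as.integer(rep(patchSize, length.out = 2))
  if (!all(checkPatchInside(center, dim(volume), patchSize)))
    stop("patch crosses the volume border at center (",
         paste(center, collapse = ", "), ")", call. = FALSE)
  ps <- patchMatrix(volume, center, patchSize, bank)
  as.numeric(ps@features[, 1])
}

#' Gabor feature matrix for a set of patch centers
#'
#' Columns follow the order of the input centers; duplicated centers give
#' identical duplicate columns. Internally each axial slice that hosts at
#' least one center is filtered once per kernel and the per-patch means are
#' read off a box-filtered magnitude image.
#'
#' @param volume a [CTVolume-class].
#' @param centers n x 3 matrix of voxel coordinates; every patch must lie
#'   fully inside the volume.
#' @param patchSize odd integer(2).
#' @param bank a [GaborBank-class].
#' @return a [PatchSet-class] with an m x n feature matrix.
#' @export
patchMatrix <- function(volume, centers, patchSize, bank) {
  stopIfNot3d(volume)
  centers <- rbindMatrix(centers)
  storage.mode(centers) <- "integer"
  if (nrow(centers) == 0L) stop("empty center list", call. = FALSE)
  patchSize <- as.integer(rep(patchSize, length.out = 2))
  if (any(patchSize %% 2L != 1L)) stop("patchSize must be odd", call. = FALSE)
  d <- dim(volume)
  if (!all(checkPatchInside(centers, d, patchSize)))
    stop("some patches cross the volume border; pre-filter centers",
         call. = FALSE)
  m <- bankSize(bank)
  featMat <- matrix(0, m, nrow(centers))
  for (z in sort(unique(centers[, 3]))) {
    inSlice <- which(centers[, 3] == z)
    slice <- volume@data[, , z]
    resp <- filterSlice(slice, bank)
    xy <- centers[inSlice, 1:2, drop = FALSE]
    for (j in seq_len(m)) {
      mm <- boxMean(abs(resp[, , j]), patchSize)
      featMat[j, inSlice] <- mm[xy]
    }
  }
  new("PatchSet", features = featMat, centers = centers,
      patchSize = patchSize)
}

#' Whole-volume Gabor magnitude feature stack
#'
#' Filters every axial slice with the full bank and box-filters the
#' magnitudes, so that `stack[x, y, z, j]` equals entry j of
#' [patchFeature()] at center (x, y, z) for interior patches. Used by the
#' pipeline to turn per-candidate feature extraction into array lookups.
#'
#' @param volume a [CTVolume-class].
#' @param bank a [GaborBank-class].
#' @param patchSize odd integer(2).
#' @param slices optional subset of z indices to compute (others left 0).
#' @return (nx, ny, nz, m) numeric array.
#' @export
gaborFeatureStack <- function(volume, bank, patchSize, slices = NULL) {
  stopIfNot3d(volume)
  patchSize <- as.integer(rep(patchSize, length.out = 2))
  d <- dim(volume)
  m <- bankSize(bank)
  if (is.null(slices)) slices <- seq_len(d[3])
  stack <- array(0, c(d, m))
  for (z in slices) {
    resp <- filterSlice(volume@data[, , z], bank)
    for (j in seq_len(m))
      stack[, , z, j] <- boxMean(abs(resp[, , j]), patchSize)
  }
  stack
}

# look up feature columns for centers from a precomputed stack
stackFeatures <- function(stack, centers) {
  m <- dim(stack)[4]
  n <- nrow(centers)
  out <- matrix(0, m, n)
  for (j in seq_len(m))
    out[j, ] <- stack[cbind(centers, j)]
  out
}
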