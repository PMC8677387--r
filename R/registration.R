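#' @include AllClasses.R utils.R
NULL

## Landmark-driven deformation: a global affine least-squares stage captures
## rigid/affine motion exactly (so e.g. a pure translation of all landmarks
## yields a constant field), and a tensor-product cubic B-spline lattice fits
## the residual displacements. With regularization weight 0 the residual fit
## is the minimum-norm exact interpolant, so each moving landmark lands on
## its fixed partner; a positive weight ridge-penalizes coefficient (hence
## displacement) magnitude.

# uniform cubic B-spline basis, evaluated at parameter u in [0,1)
cubicBsplineBasis <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# basis matrix (length(x) x nCtrl) for control points at
# grid0 + (0:(nCtrl-1)) * h, cubic B-spline with unit knot spacing h
bsplineBasisMatrix <- function(x, grid0, h, nCtrl) {
  tpar <- (x - grid0) / h
  cell <- floor(tpar)
  u <- tpar - cell
  B <- cubicBsplineBasis(u)
  M <- matrix(0, length(x), nCtrl)
  for (k in 0:3) {
    col <- as.integer(cell) + k + 1L   # control index (1-based)
    ok <- col >= 1L & col <= nCtrl
    M[cbind(which(ok), col[ok])] <- M[cbind(which(ok), col[ok])] + B[ok, k + 1L]
  }
  M
}

#' Fit a landmark-driven B-spline deformation field
#'
#' Builds the displacement field on the target grid from paired landmarks:
#' global affine least squares plus a cubic B-spline lattice fitted to the
#' residuals. Pull-back convention: the field maps target-grid positions to
#' their source location in the training image, so resampling reads
#' `training(x + displacement(x))`.
#'
#' With `regularizationWeight = 0` the fitted field reproduces each fixed
#' landmark's displacement exactly (minimum-norm interpolation); increasing
#' the weight shrinks the B-spline displacement magnitude.
#'
#' @param landmarks a [LandmarkSet-class] (moving = training mm, fixed =
#'   target mm).
#' @param target a [CTVolume-class] (or mask) defining the output grid.
#' @param controlSpacing mm between B-spline control points.
#' @param regularizationWeight ridge penalty on B-spline coefficients.
#' @return a [DeformationField-class] on the target grid.
#' @examples
#' v <- ctVolume(array(0, c(8, 8, 8)))
#' lm <- landmarkSet(matrix(runif(15, 2, 5), 5), matrix(runif(15, 2, 5), 5))
#' f <- fitLandmarkDeformation(lm, v)
#' @export
fitLandmarkDeformation <- function(landmarks, target, controlSpacing = 24,
                                   regularizationWeight = 0) {
  stopifnot(is(landmarks, "LandmarkSet"))
  stopIfNot3d(target, "target")
  if (controlSpacing <= 0) stop("controlSpacing must be positive", call. = FALSE)
  fx <- landmarks@fixed
  disp <- landmarks@moving - fx   # pull-back displacement at target points
  n <- nrow(fx)

  ## affine stage: disp ~ A x + b, least squares
  X <- cbind(fx, 1)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    warning("degenerate (coplanar) landmark configuration; ",
            "using least-squares affine fit", call. = FALSE)
    Ab <- MASS_ginv(X) %*% disp
  } else {
    Ab <- qr.coef(qrX, disp)
  }
  Ab[!is.finite(Ab)] <- 0
  affineAt <- function(P) cbind(P, 1) %*% Ab
  resid <- disp - affineAt(fx)

  d <- dim(target)
  sp <- spacing(target); org <- origin(target)
  ext0 <- org; ext1 <- org + (d - 1) * sp
  h <- controlSpacing

  ## control lattice padded so the cubic support covers the whole grid
  nCtrl <- integer(3); grid0 <- numeric(3)
  for (a in 1:3) {
    grid0[a] <- ext0[a] - 2 * h
    nCtrl[a] <- ceiling((ext1[a] - grid0[a]) / h) + 4L
  }

  useSpline <- max(abs(resid)) > 1e-12
  coef <- array(0, nCtrl)
  if (useSpline) {
    Bx <- bsplineBasisMatrix(fx[, 1], grid0[1], h, nCtrl[1])
    By <- bsplineBasisMatrix(fx[, 2], grid0[2], h, nCtrl[2])
    Bz <- bsplineBasisMatrix(fx[, 3], grid0[3], h, nCtrl[3])
    ## row i of Phi = Bx[i,] (x) By[i,] (x) Bz[i,] (Khatri-Rao)
    Phi <- matrix(0, n, prod(nCtrl))
    for (i in seq_len(n))
      Phi[i, ] <- as.vector(outer(outer(Bx[i, ], By[i, ]), Bz[i, ]))
    G <- Phi %*% t(Phi) + diag(regularizationWeight + 1e-10, n)
  }

  evalComp <- function(compResid) {
    if (!useSpline) return(NULL)
    w <- crossprod(Phi, solve(G, compResid))  # min-norm / ridge solution
    array(w, nCtrl)
  }

  ## evaluate on the grid, separably per axis
  gx <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  gy <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  gz <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  if (useSpline) {
    Gx <- bsplineBasisMatrix(gx, grid0[1], h, nCtrl[1])
    Gy <- bsplineBasisMatrix(gy, grid0[2], h, nCtrl[2])
    Gz <- bsplineBasisMatrix(gz, grid0[3], h, nCtrl[3])
  }
  contract <- function(C) {
    ## C: (ncx, ncy, ncz) -> field on (nx, ny, nz)
    t1 <- Gx %*% matrix(C, nCtrl[1])                       # nx x (ncy*ncz)
    t1 <- array(t1, c(d[1], nCtrl[2], nCtrl[3]))
    t2 <- apply(t1, c(1, 3), function(v) Gy %*% v)         # ny x nx x ncz
    t2 <- aperm(t2, c(2, 1, 3))
    t3 <- apply(t2, c(1, 2), function(v) Gz %*% v)         # nz x nx x ny
    aperm(t3, c(2, 3, 1))
  }

  displacement <- array(0, c(d, 3))
  ## affine part on the grid (outer sums, no n^3 x 3 matrix build)
  for (comp in 1:3) {
    A <- Ab[1:3, comp]; b <- Ab[4, comp]
    affGrid <- outer(outer(A[1] * gx, A[2] * gy, "+"), A[3] * gz, "+") + b
    if (useSpline) {
      C <- evalComp(resid[, comp])
      affGrid <- affGrid + contract(C)
    }
    displacement[, , , comp] <- affGrid
  }

  new("DeformationField", displacement = displacement, spacing = sp,
      origin = org, controlSpacing = as.numeric(controlSpacing))
}

# Moore-Penrose pseudoinverse via SVD (rank-deficient affine fallback)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Evaluate a deformation field at arbitrary physical points
#'
#' Trilinear interpolation of the displacement grid.
#'
#' @param field a [DeformationField-class].
#' @param pointsMM n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of mm displacements.
#' @export
evalDeformation <- function(field, pointsMM) {
  pointsMM <- rbindMatrix(pointsMM)
  vox <- physToVoxel(pointsMM, field)
  out <- matrix(0, nrow(pointsMM), 3)
  for (comp in 1:3)
    out[, comp] <- interpTrilinear(field@displacement[, , , comp], vox)
  out
}

#' Warp a volume or mask through a deformation field
#'
#' Resamples `image` onto the field's target grid with the pull-back
#' convention: `output(x) = image(x + displacement(x))`. Masks must use
#' nearest-neighbor interpolation so the value set \{0, 1\} is preserved;
#' requesting linear interpolation for a mask is an error.
#'
#' @param field a [DeformationField-class] (defines the output grid).
#' @param image a [CTVolume-class] or [CTMask-class] (its own geometry may
#'   differ from the target grid).
#' @param interpolation "linear" or "nearest".
#' @return warped [CTVolume-class] / [CTMask-class] on the target grid.
#' @export
applyDeformation <- function(field, image,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopIfNot3d(image, "image")
  isMask <- is(image, "CTMask")
  if (isMask && interpolation == "linear")
    stop("linear interpolation would break mask binarity; use 'nearest'",
         call. = FALSE)
  d <- dim(field@displacement)[1:3]
  sp <- field@spacing; org <- field@origin
  ## target physical coordinates plus displacement -> source voxel coords
  gx <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  gy <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  gz <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  P <- cbind(rep(gx, times = d[2] * d[3]),
             rep(rep(gy, each = d[1]), times = d[3]),
             rep(gz, each = d[1] * d[2]))
  P <- P + cbind(as.vector(field@displacement[, , , 1]),
                 as.vector(field@displacement[, , , 2]),
                 as.vector(field@displacement[, , , 3]))
  vox <- physToVoxel(P, image)
  vals <- if (interpolation == "linear") interpTrilinear(image@data, vox)
          else interpNearest(image@data, vox)
  arr <- array(vals, d)
  if (isMask) ctMask(arr, sp, org) else ctVolume(arr, sp, org)
}

#' Extract the 6-neighborhood surface of a mask
#'
#' Returns exactly the foreground voxels that have at least one background
#' voxel among their 6 face neighbors; voxels on the volume border count
#' out-of-bounds neighbors as background, so a full-volume mask still has an
#' outer-shell surface.
#'
#' @param mask a non-empty [CTMask-class].
#' @param source provenance tag for the returned points.
#' @return a [BoundaryPoints-class].
#' @examples
#' m <- array(0, c(7, 7, 7)); m[2:6, 2:6, 2:6] <- 1
#' nElements(extractSurfacePoints(ctMask(m)))  # 5^3 - 3^3 = 98
#' @export
extractSurfacePoints <- function(mask, source = "prior") {
  stopifnot(is(mask, "CTMask"))
  fg <- mask@data > 0.5
  if (!any(fg)) stop("mask is empty", call. = FALSE)
  surf <- fg & neighborAny(!fg, fill = TRUE)
  boundaryPoints(which(surf, arr.ind = TRUE), source = source)
}

#' Serialize a deformation field to NIfTI
#'
#' Written as a 4D volume with 3 displacement components (mm).
#'
#' @param field a [DeformationField-class].
#' @param path destination `.nii`/`.nii.gz`.
#' @return invisibly, `path`.
#' @export
writeDeformationField <- function(field, path) {
  img <- RNifti::asNifti(field@displacement)
  xf <- structure(diag(c(field@spacing, 1)), code = 2L)
  xf[1:3, 4] <- field@origin
  img <- RNifti::`qform<-`(img, value = xf)
  img <- RNifti::`pixdim<-`(img, value = c(field@spacing, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a deformation field written by [writeDeformationField()]
#'
#' @param path a 4D NIfTI with 3 displacement channels.
#' @param controlSpacing mm; recorded on the returned object.
#' @return a [DeformationField-class].
#' @export
readDeformationField <- function(path, controlSpacing = 24) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop("expected a 4D NIfTI with 3 displacement channels: ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  new("DeformationField", displacement = array(as.numeric(img), dim(img)),
      spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4],
      controlSpacing = as.numeric(controlSpacing))
}
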