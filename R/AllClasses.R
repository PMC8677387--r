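#' @useDynLib GaborDictSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Volumes and masks
## ---------------------------------------------------------------------------

#' CTVolume: a 3D scalar image with physical geometry
#'
#' A `CTVolume` holds a 3D array of intensities (Hounsfield-like arbitrary
#' units) together with its voxel spacing and physical origin. Voxel indices
#' are 1-based; the physical position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing` (axis-aligned geometry, no direction
#' cosines). All other classes in the package consume this geometry.
#'
#' @slot data 3D numeric array, finite everywhere.
#' @slot spacing numeric(3), mm per voxel along (x, y, z); strictly positive.
#' @slot origin numeric(3), mm position of voxel (1, 1, 1).
#'
#' @seealso [ctVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("CTVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 1L)) return("all shape components must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  if (anyNA(d) || any(!is.finite(d))) return("voxel data must be finite")
  TRUE
})

#' CTMask: a binary 3D mask
#'
#' A [CTVolume-class] whose voxels are restricted to \{0, 1\}. Used for the
#' gold-standard liver label, the warped prior, and segmentation outputs.
#'
#' @seealso [ctMask()]
#' @export
setClass("CTMask", contains = "CTVolume")

setValidity("CTMask", function(object) {
  v <- unique(as.vector(object@data))
  if (!all(v %in% c(0, 1))) return("mask values must be in {0, 1}")
  TRUE
})

#' LandmarkSet: paired anatomical landmarks in physical mm
#'
#' Rows of `moving` and `fixed` correspond: `moving[i, ]` is a point in the
#' training image, `fixed[i, ]` its anatomical match in the target image.
#' Stored in physical mm so the two volumes may differ in spacing.
#'
#' @slot moving n x 3 matrix of mm coordinates in the training image.
#' @slot fixed n x 3 matrix of mm coordinates in the target image.
#' @export
setClass("LandmarkSet",
  representation(moving = "matrix", fixed = "matrix"))

setValidity("LandmarkSet", function(object) {
  m <- object@moving; f <- object@fixed
  if (ncol(m) != 3L || ncol(f) != 3L) return("landmark matrices must have 3 columns")
  if (nrow(m) != nrow(f)) return("moving and fixed must pair row-for-row")
  if (nrow(m) < 4L) return("at least 4 landmark pairs are required")
  if (anyNA(m) || anyNA(f)) return("landmarks must be numeric and finite")
  if (anyDuplicated(round(m, 9))) return("duplicate moving points are not allowed")
  TRUE
})

## ---------------------------------------------------------------------------
## Registration
## ---------------------------------------------------------------------------

#' DeformationField: per-voxel displacement on a target grid
#'
#' Pull-back convention: the displacement at a target-grid point gives the
#' mm offset to the corresponding location in the moving (training) image,
#' i.e. resampling reads `moving(x + displacement(x))`.
#'
#' @slot displacement 4D array (nx, ny, nz, 3) of mm displacements.
#' @slot spacing,origin geometry of the target grid (as in [CTVolume-class]).
#' @slot controlSpacing mm between B-spline control points used in the fit.
#' @export
setClass("DeformationField",
  representation(displacement = "array", spacing = "numeric",
                 origin = "numeric", controlSpacing = "numeric"))

setValidity("DeformationField", function(object) {
  d <- object@displacement
  if (length(dim(d)) != 4L || dim(d)[4] != 3L)
    return("displacement must be an (nx, ny, nz, 3) array")
  if (any(!is.finite(d))) return("displacement must be finite everywhere")
  if (object@controlSpacing <= 0) return("controlSpacing must be positive")
  TRUE
})

#' BoundaryPoints: a set of voxel coordinates on a surface
#'
#' Integer voxel coordinates (1-based) on the grid of a target volume,
#' tagged by provenance: the warped-prior surface or the dictionary-predicted
#' boundary.
#'
#' @slot points n x 3 integer matrix of voxel coordinates.
#' @slot source one of "prior" or "predicted".
#' @export
setClass("BoundaryPoints",
  representation(points = "matrix", source = "character"))

setValidity("BoundaryPoints", function(object) {
  p <- object@points
  if (ncol(p) != 3L) return("points must have 3 columns")
  if (nrow(p) < 1L) return("point set must be non-empty")
  if (any(p != round(p))) return("points must be integer voxel coordinates")
  if (anyDuplicated(p)) return("duplicate points are not allowed")
  if (!object@source %in% c("prior", "predicted"))
    return("source must be 'prior' or 'predicted'")
  TRUE
})

## ---------------------------------------------------------------------------
## Gabor features
## ---------------------------------------------------------------------------

#' GaborBank: a bank of 2D even-symmetric Gabor kernels
#'
#' Kernels are real (cosine-phase), DC-corrected to zero mean and normalized
#' to unit L2 norm, so constant image regions give exactly zero response.
#' Kernel `j` corresponds to orientation `orientationOf(j)` and wavelength
#' `wavelengthOf(j)` with scale-major ordering:
#' `j = (scale - 1) * nOrientations + orientation`.
#'
#' @slot kernels list of m = nOrientations * nScales square matrices.
#' @slot orientations radians in [0, pi).
#' @slot wavelengths voxels per cycle, strictly increasing, one per scale.
#' @slot sigmaFactor Gaussian envelope sigma as a fraction of wavelength.
#' @slot kernelRadius half-width of each kernel in voxels.
#' @seealso [gaborBankSpec()], [buildGaborBank()]
#' @export
setClass("GaborBank",
  representation(kernels = "list", orientations = "numeric",
                 wavelengths = "numeric", sigmaFactor = "numeric",
                 kernelRadius = "integer"))

#' PatchSet: Gabor feature columns with their patch centers
#'
#' The training matrix (patches on the gold-standard boundary) and the test
#' matrix (patches around prior-boundary candidates) are both `PatchSet`s:
#' an m x N feature matrix whose column i describes the in-plane patch of
#' size `patchSize` centered at voxel `centers[i, ]`.
#'
#' @slot features m x N numeric matrix, columns are per-patch feature vectors.
#' @slot centers N x 3 integer matrix of patch-center voxel coordinates.
#' @slot patchSize integer(2), in-plane (x, y) patch extent, odd.
#' @export
setClass("PatchSet",
  representation(features = "matrix", centers = "matrix",
                 patchSize = "integer"))

setValidity("PatchSet", function(object) {
  if (ncol(object@features) != nrow(object@centers))
    return("one center per feature column is required")
  if (any(!is.finite(object@features))) return("features must be finite")
  if (length(object@patchSize) != 2L || any(object@patchSize %% 2L != 1L))
    return("patchSize must be two odd integers")
  TRUE
})

## ---------------------------------------------------------------------------
## Sparse dictionary
## ---------------------------------------------------------------------------

#' GaborDictionary: an overcomplete dictionary of unit-norm atoms
#'
#' The m x t matrix D of the sparse model Y ~ D X with column-sparsity
#' bound T0. Overcompleteness (m < t) is required: the dictionary must span
#' boundary-patch feature space redundantly.
#'
#' @slot atoms m x t numeric matrix with unit-L2-norm columns.
#' @export
setClass("GaborDictionary", representation(atoms = "matrix"))

setValidity("GaborDictionary", function(object) {
  D <- object@atoms
  if (nrow(D) >= ncol(D)) return("dictionary must be overcomplete (m < t)")
  n <- sqrt(colSums(D^2))
  if (any(abs(n - 1) > 1e-10)) return("all atom columns must have unit L2 norm")
  TRUE
})

#' SparseCodes: sparse coefficient matrix with its sparsity bound
#'
#' @slot codes t x N matrix X; every column has at most `sparsity` nonzeros.
#' @slot sparsity the bound T0.
#' @export
setClass("SparseCodes",
  representation(codes = "matrix", sparsity = "integer"))

setValidity("SparseCodes", function(object) {
  nnz <- colSums(object@codes != 0)
  if (any(nnz > object@sparsity))
    return("a code column exceeds the sparsity bound T0")
  TRUE
})

#' KSVDConfig: parameters of K-SVD dictionary training
#'
#' @slot t number of atoms (dictionary columns).
#' @slot T0 sparsity bound per code column (L0).
#' @slot nIterations maximum alternation count.
#' @slot seed integer seed controlling dictionary initialization.
#' @slot replaceUnusedAtoms replace never-selected atoms by the currently
#'   worst-reconstructed training sample (standard degeneracy handling).
#' @seealso [ksvdConfig()], [ksvdTrain()]
#' @export
setClass("KSVDConfig",
  representation(t = "integer", T0 = "integer", nIterations = "integer",
                 seed = "integer", replaceUnusedAtoms = "logical"))

setValidity("KSVDConfig", function(object) {
  if (object@T0 < 1L) return("T0 must be >= 1")
  if (object@t < 1L) return("t must be >= 1")
  if (object@nIterations < 1L) return("nIterations must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Boundary candidates
## ---------------------------------------------------------------------------

#' CandidateSet: axis-neighborhood candidates per prior-boundary vertex
#'
#' For every vertex of the prior boundary, the candidate centers are the
#' vertex's axis neighbors `v +- k * e_axis`, `k = 1..radius`, clipped to the
#' volume; radius 5 gives the standard 30 neighborhood points per vertex.
#'
#' @slot candidates n x 3 integer matrix of candidate voxel coordinates.
#' @slot vertex integer(n), row index of the generating vertex.
#' @slot vertices the generating vertex coordinates (one row per vertex).
#' @slot radius the neighborhood radius used.
#' @export
setClass("CandidateSet",
  representation(candidates = "matrix", vertex = "integer",
                 vertices = "matrix", radius = "integer"))

## ---------------------------------------------------------------------------
## Void filling
## ---------------------------------------------------------------------------

#' Octree: adaptive decomposition of a volume's bounding cube
#'
#' Scan-conversion octree over the shell mask: nodes intersecting the shell
#' are refined to `maxDepth` (so every shell/decomposition-line intersection
#' sits on a finest leaf), homogeneous empty regions stay coarse. Leaves
#' partition the root cube.
#'
#' @slot leaves data.frame with columns x0, y0, z0 (1-based corner voxel),
#'   size (edge length in finest cells), depth, intersects (logical).
#' @slot maxDepth maximum subdivision depth.
#' @slot dims the voxel dimensions of the underlying volume.
#' @slot rootSize edge length of the (padded, power-of-two) root cube.
#' @export
setClass("Octree",
  representation(leaves = "data.frame", maxDepth = "integer",
                 dims = "integer", rootSize = "integer"))

#' SurfaceMesh: a triangle mesh in physical mm
#'
#' @slot vertices n x 3 matrix of mm coordinates.
#' @slot faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals).
#' @seealso [isWatertight()], [meshVolume()], [writeMeshSTL()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be triangles (m x 3)")
  f <- object@faces
  if (nrow(f) > 0 && (min(f) < 1 || max(f) > nrow(object@vertices)))
    return("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return("degenerate faces are not allowed")
  TRUE
})

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

#' MetricsReport: the five MICCAI 2007 segmentation metrics
#'
#' Volumetric overlap error and relative volume difference in percent;
#' average / root-mean-square / maximum symmetric surface distances in mm.
#'
#' @slot voe,rvd percent.
#' @slot assd,rmsssd,mssd mm.
#' @seealso [computeMetrics()], [aggregateMetrics()]
#' @export
setClass("MetricsReport",
  representation(voe = "numeric", rvd = "numeric", assd = "numeric",
                 rmsssd = "numeric", mssd = "numeric"))

setValidity("MetricsReport", function(object) {
  if (object@voe < 0 || object@voe > 100) return("voe must be in [0, 100]")
  if (object@assd < 0 || object@rmsssd < 0 || object@mssd < 0)
    return("surface distances must be non-negative")
  tol <- 1e-9
  if (object@assd > object@rmsssd + tol || object@rmsssd > object@mssd + tol)
    return("assd <= rmsssd <= mssd must hold (power-mean inequality)")
  TRUE
})

## ---------------------------------------------------------------------------
## Phantom and pipeline configuration
## ---------------------------------------------------------------------------

#' PhantomSpec: parameters of the synthetic CT phantom
#'
#' The generator emulates the paired-study setting: one "training" abdomen
#' with a gold-standard organ mask, one "target" abdomen produced by a known
#' smooth deformation, matched landmarks, and an intensity model in which the
#' organ boundary carries an oriented texture band (so Gabor features are
#' informative) while the background contains a confuser blob of similar mean
#' intensity but different texture.
#'
#' @slot shape voxel dimensions.
#' @slot spacing mm per voxel.
#' @slot organCenter,organRadii mm; superellipsoid center and semi-axes.
#' @slot organExponent superellipsoid exponent (2 = ellipsoid).
#' @slot contrast organ-vs-background mean intensity gap.
#' @slot noiseSigma additive Gaussian noise SD.
#' @slot textureAmplitude,textureWavelength boundary grating parameters
#'   (intensity units; voxels per cycle).
#' @slot bandWidth half-width of the boundary texture band in voxels.
#' @slot deformAmplitude mm amplitude of the true low-frequency deformation.
#' @slot nLandmarks number of landmark pairs to sample.
#' @slot seed integer seed.
#' @seealso [phantomSpec()], [makePhantomPair()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 organCenter = "numeric", organRadii = "numeric",
                 organExponent = "numeric", contrast = "numeric",
                 noiseSigma = "numeric", textureAmplitude = "numeric",
                 textureWavelength = "numeric", bandWidth = "numeric",
                 deformAmplitude = "numeric", nLandmarks = "integer",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (any(object@organRadii <= 0)) return("organRadii must be positive")
  lo <- object@organCenter - object@organRadii
  hi <- object@organCenter + object@organRadii
  ext <- (object@shape - 1) * object@spacing
  margin <- 8 * object@spacing  # >= patch half-width + kernel support
  if (any(lo < margin) || any(hi > ext - margin))
    return("organ must lie inside the volume with a patch-sized margin")
  TRUE
})

#' PipelineConfig: all tunables of the end-to-end segmentation
#'
#' @slot gabor a [GaborBank-class] specification (built bank).
#' @slot ksvd a [KSVDConfig-class].
#' @slot patchSize integer(2), odd in-plane patch extent.
#' @slot nTraining training patches sampled on the gold boundary.
#' @slot candidateRadius axis-neighborhood radius (5 gives 30 candidates).
#' @slot dilation shell dilation radius (L1 ball) before void filling.
#' @slot maxDepth octree depth; NA means finest leaves of ~1 voxel.
#' @slot smoothWidth surface-regularization window for void filling.
#' @slot pruneDelta mm tolerance for redundant-point pruning.
#' @slot seed master seed propagated to every stochastic stage.
#' @seealso [pipelineConfig()], [runSegmentation()]
#' @export
setClass("PipelineConfig",
  representation(gabor = "GaborBank", ksvd = "KSVDConfig",
                 patchSize = "integer", nTraining = "integer",
                 candidateRadius = "integer", dilation = "integer",
                 maxDepth = "integer", smoothWidth = "integer",
                 pruneDelta = "numeric", seed = "integer"))
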