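#' @include AllClasses.R
NULL

#' Accessors for image geometry and contents
#'
#' `imgData` returns the raw array, `spacing` the mm voxel spacing, `origin`
#' the mm position of voxel (1,1,1). `dim` on a [CTVolume-class] gives the
#' voxel shape.
#'
#' @param x a [CTVolume-class], [CTMask-class] or [DeformationField-class].
#' @return array / numeric(3) as appropriate.
#' @aliases imgData spacing origin
#' @name geometry-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname geometry-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname geometry-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname geometry-accessors
setMethod("imgData", "CTVolume", function(x) x@data)
#' @rdname geometry-accessors
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname geometry-accessors
setMethod("origin", "CTVolume", function(x) x@origin)
#' @rdname geometry-accessors
setMethod("dim", "CTVolume", function(x) dim(x@data))
#' @rdname geometry-accessors
setMethod("spacing", "DeformationField", function(x) x@spacing)
#' @rdname geometry-accessors
setMethod("origin", "DeformationField", function(x) x@origin)

#' Number of elements in a container
#'
#' Landmark pairs in a [LandmarkSet-class], points in a
#' [BoundaryPoints-class], patches in a [PatchSet-class].
#'
#' @param x the container.
#' @return integer count.
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @rdname nElements
setMethod("nElements", "LandmarkSet", function(x) nrow(x@moving))
#' @rdname nElements
setMethod("nElements", "BoundaryPoints", function(x) nrow(x@points))
#' @rdname nElements
setMethod("nElements", "PatchSet", function(x) ncol(x@features))

#' Landmark coordinate accessors
#'
#' @param x a [LandmarkSet-class].
#' @return n x 3 matrix of mm coordinates.
#' @export
setGeneric("movingPoints", function(x) standardGeneric("movingPoints"))
#' @rdname movingPoints
#' @export
setGeneric("fixedPoints", function(x) standardGeneric("fixedPoints"))
#' @rdname movingPoints
setMethod("movingPoints", "LandmarkSet", function(x) x@moving)
#' @rdname movingPoints
setMethod("fixedPoints", "LandmarkSet", function(x) x@fixed)

#' Boundary point coordinates
#'
#' @param x a [BoundaryPoints-class].
#' @return n x 3 integer matrix of voxel coordinates.
#' @export
setGeneric("boundaryCoords", function(x) standardGeneric("boundaryCoords"))
#' @rdname boundaryCoords
setMethod("boundaryCoords", "BoundaryPoints", function(x) x@points)

#' Dictionary, code, and patch accessors
#'
#' @param x a [GaborDictionary-class], [SparseCodes-class] or
#'   [PatchSet-class].
#' @return the underlying matrix.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname atoms
setMethod("atoms", "GaborDictionary", function(x) x@atoms)
#' @rdname atoms
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))
#' @rdname atoms
setMethod("codes", "SparseCodes", function(x) x@codes)
#' @rdname atoms
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname atoms
setMethod("features", "PatchSet", function(x) x@features)
#' @rdname atoms
#' @export
setGeneric("patchCenters", function(x) standardGeneric("patchCenters"))
#' @rdname atoms
setMethod("patchCenters", "PatchSet", function(x) x@centers)

#' Mesh accessors
#'
#' @param x a [SurfaceMesh-class].
#' @return vertex / face matrix.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname meshVertices
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname meshVertices
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname meshVertices
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' Metrics as a named vector
#'
#' @param x a [MetricsReport-class].
#' @return named numeric(5): voe, rvd, assd, rmsssd, mssd.
#' @export
setGeneric("metricsVector", function(x) standardGeneric("metricsVector"))
#' @rdname metricsVector
setMethod("metricsVector", "MetricsReport", function(x)
  c(voe = x@voe, rvd = x@rvd, assd = x@assd, rmsssd = x@rmsssd,
    mssd = x@mssd))

## show methods -------------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  cat(sprintf("%s %s | spacing %s mm | origin %s mm | range [%.4g, %.4g]\n",
              class(object), paste(dim(object@data), collapse = "x"),
              paste(format(object@spacing), collapse = ", "),
              paste(format(object@origin), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet with %d paired points (mm)\n", nrow(object@moving)))
})

setMethod("show", "BoundaryPoints", function(object) {
  cat(sprintf("BoundaryPoints (%s): %d voxels\n", object@source,
              nrow(object@points)))
})

setMethod("show", "GaborBank", function(object) {
  cat(sprintf(
    "GaborBank: %d orientations x %d scales = %d kernels (radius %d voxels)\n",
    length(object@orientations), length(object@wavelengths),
    length(object@kernels), object@kernelRadius))
})

setMethod("show", "GaborDictionary", function(object) {
  cat(sprintf("GaborDictionary: %d x %d (feature dim x atoms)\n",
              nrow(object@atoms), ncol(object@atoms)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %dx%d, feature length %d\n",
              ncol(object@features), object@patchSize[1], object@patchSize[2],
              nrow(object@features)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (isWatertight(object)) " (watertight)" else ""))
})

setMethod("show", "MetricsReport", function(object) {
  v <- metricsVector(object)
  cat(sprintf("VOE %.2f%% | RVD %.2f%% | ASSD %.3f mm | RMSSSD %.3f mm | MSSD %.3f mm\n",
              v[1], v[2], v[3], v[4], v[5]))
})

setMethod("show", "Octree", function(object) {
  cat(sprintf("Octree: %d leaves (max depth %d, root %d^3 cells)\n",
              nrow(object@leaves), object@maxDepth, object@rootSize))
})
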