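#' @include AllClasses.R utils.R gabor.R sparse-dictionary.R boundary.R
#' @include void-filling.R evaluation.R registration.R
NULL

#' Assemble the full pipeline configuration
#'
#' @param gabor a [GaborBank-class] (default bank: 6 orientations x 4
#'   scales).
#' @param ksvd a [KSVDConfig-class]. The pipeline default uses a smaller,
#'   sparser dictionary (48 atoms, T0 = 2) than the module-level K-SVD
#'   default: with unit-norm patch features, looser sparse models
#'   reconstruct off-boundary patches too well and flatten the
#'   reconstruction-error contrast that drives boundary selection.
#' @param patchSize odd integer(2) in-plane patch extent.
#' @param nTraining training patches sampled on the gold boundary.
#' @param candidateRadius axis-neighborhood radius (5 -> 30 candidates per
#'   prior vertex).
#' @param dilation shell dilation before void filling (L1 ball radius).
#' @param maxDepth octree depth (NA = single-voxel finest leaves).
#' @param smoothWidth void-filling surface regularization window (voxels).
#' @param pruneDelta mm tolerance for redundant-point pruning.
#' @param controlSpacing mm between registration B-spline control points.
#' @param regularizationWeight ridge weight of the deformation fit.
#' @param seed master seed; every stochastic stage derives from it.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(gabor = buildGaborBank(),
                           ksvd = ksvdConfig(t = 48L, T0 = 2L),
                           patchSize = c(9L, 9L), nTraining = 1000L,
                           candidateRadius = 5L, dilation = 1L,
                           maxDepth = NA, smoothWidth = 7L, pruneDelta = 2,
                           controlSpacing = 24, regularizationWeight = 0,
                           seed = 1L) {
  cfg <- new("PipelineConfig", gabor = gabor, ksvd = ksvd,
             patchSize = as.integer(rep(patchSize, length.out = 2)),
             nTraining = as.integer(nTraining),
             candidateRadius = as.integer(candidateRadius),
             dilation = as.integer(dilation),
             maxDepth = as.integer(if (is.na(maxDepth)) -1L else maxDepth),
             smoothWidth = as.integer(smoothWidth),
             pruneDelta = as.numeric(pruneDelta), seed = as.integer(seed))
  attr(cfg, "controlSpacing") <- controlSpacing
  attr(cfg, "regularizationWeight") <- regularizationWeight
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized keys (all optional): `gabor` (nOrientations, wavelengths,
#' sigmaFactor, kernelRadius), `ksvd` (t, T0, nIterations,
#' replaceUnusedAtoms), `patchSize`, `nTraining`, `candidateRadius`,
#' `dilation`, `maxDepth`, `pruneDelta`, `controlSpacing`,
#' `regularizationWeight`, `seed`.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  g <- cfg$gabor %||% list()
  bank <- buildGaborBank(do.call(gaborBankSpec, g))
  k <- cfg$ksvd %||% list()
  if (!is.null(cfg$seed) && is.null(k$seed)) k$seed <- cfg$seed
  kc <- do.call(ksvdConfig, k)
  args <- cfg[setdiff(names(cfg), c("gabor", "ksvd", "paths"))]
  do.call(pipelineConfig, c(list(gabor = bank, ksvd = kc), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end prior-boundary segmentation
#'
#' Orchestrates the whole flow: fit the landmark deformation, warp the
#' gold-standard mask into the target volume, extract the prior boundary,
#' sample training patches on the training gold boundary (Gabor features),
#' train the K-SVD dictionary, score axis-neighborhood candidates around
#' the prior boundary by OMP reconstruction error, keep the per-vertex
#' minima as predicted boundary points, and repair the point cloud into a
#' watertight surface and solid mask by octree parity labelling and dual
#' contouring. If a target gold mask is supplied, the five evaluation
#' metrics are computed.
#'
#' @param trainingVolume,trainingMask the atlas CT and its gold standard.
#' @param targetVolume the CT to segment (defines the output grid).
#' @param landmarks a [LandmarkSet-class] pairing training and target.
#' @param config a [PipelineConfig-class].
#' @param targetGoldMask optional gold standard for evaluation.
#' @param verbose emit per-stage messages.
#' @return list with `mask` (solid [CTMask-class]), `mesh`
#'   ([SurfaceMesh-class]), `boundary` (predicted [BoundaryPoints-class],
#'   pruned), `rawBoundary` (pre-pruning), `priorMask`, `field`,
#'   `metrics` (a [MetricsReport-class] or NULL), and `log` (data.frame of
#'   stage records).
#' @export
runSegmentation <- function(trainingVolume, trainingMask, targetVolume,
                            landmarks, config = pipelineConfig(),
                            targetGoldMask = NULL, verbose = TRUE) {
  stopIfNot3d(trainingVolume, "trainingVolume")
  stopifnot(is(trainingMask, "CTMask"))
  stopIfNot3d(targetVolume, "targetVolume")
  logRows <- list()
  t0 <- proc.time()[3]
  stage <- function(name, detail) {
    if (verbose) message(sprintf("[%6.1fs] %s: %s", proc.time()[3] - t0,
                                 name, detail))
    logRows[[length(logRows) + 1L]] <<- data.frame(
      stage = name, detail = detail, elapsed = proc.time()[3] - t0)
  }
  run <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cs <- attr(config, "controlSpacing") %||% 24
  rw <- attr(config, "regularizationWeight") %||% 0

  field <- run("register", fitLandmarkDeformation(landmarks, targetVolume,
                                                  controlSpacing = cs,
                                                  regularizationWeight = rw))
  stage("register", sprintf("%d landmarks, control spacing %g mm",
                            nElements(landmarks), cs))

  priorMask <- run("warp-gold",
                   applyDeformation(field, trainingMask, "nearest"))
  prior <- run("prior-boundary", extractSurfacePoints(priorMask, "prior"))
  stage("prior-boundary", sprintf("%d prior surface voxels",
                                  nElements(prior)))

  bank <- config@gabor
  train <- run("training-patches",
               sampleTrainingPatches(trainingVolume, trainingMask,
                                     config@patchSize, config@nTraining,
                                     seed = config@seed + 11L, bank = bank))
  stage("training-patches", sprintf("%d patches of %dx%d",
                                    nElements(train), config@patchSize[1],
                                    config@patchSize[2]))

  fit <- run("ksvd", ksvdTrain(train, config@ksvd))
  stage("ksvd", sprintf("t=%d T0=%d, objective %.4g after %d iterations",
                        config@ksvd@t, config@ksvd@T0,
                        utils::tail(fit$objective, 1),
                        length(fit$objective)))

  cands <- run("candidates",
               candidateCenters(prior, config@candidateRadius,
                                dim(targetVolume)))
  stage("candidates", sprintf("%d candidates (radius %d)",
                              nrow(cands@candidates), config@candidateRadius))

  ## Gabor-filter only the slices that host candidates
  zUsed <- sort(unique(cands@candidates[, 3]))
  stack <- run("gabor-target",
               gaborFeatureStack(targetVolume, bank, config@patchSize,
                                 slices = zUsed))
  stage("gabor-target", sprintf("%d slices filtered with %d kernels",
                                length(zUsed), bankSize(bank)))

  predicted <- run("select-boundary",
                   selectBoundaryPoints(cands, targetVolume,
                                        config@patchSize, fit$dictionary,
                                        config@ksvd@T0, bank = bank,
                                        featureStack = stack))
  stage("select-boundary", sprintf("%d predicted boundary points",
                                   nElements(predicted)))

  maxDepth <- if (config@maxDepth < 0L) NA else config@maxDepth
  filled <- run("fill-voids",
                fillVoids(predicted, dim(targetVolume),
                          spacing = spacing(targetVolume),
                          origin = origin(targetVolume),
                          dilation = config@dilation, maxDepth = maxDepth,
                          smoothWidth = config@smoothWidth))
  stage("fill-voids", sprintf("solid %d voxels, mesh %d faces",
                              sum(filled$mask@data), nrow(filled$mesh@faces)))

  pruned <- run("prune", pruneRedundantPoints(predicted, filled$mesh,
                                              config@pruneDelta,
                                              spacing(targetVolume),
                                              origin(targetVolume)))
  stage("prune", sprintf("%d of %d points kept (delta %g mm)",
                         nElements(pruned), nElements(predicted),
                         config@pruneDelta))

  metrics <- NULL
  if (!is.null(targetGoldMask)) {
    metrics <- run("evaluate", computeMetrics(filled$mask, targetGoldMask))
    stage("evaluate", sprintf("VOE %.2f%%", metrics@voe))
  }
  list(mask = filled$mask, mesh = filled$mesh, boundary = pruned,
       rawBoundary = predicted, priorMask = priorMask, field = field,
       metrics = metrics, log = do.call(rbind, logRows))
}
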