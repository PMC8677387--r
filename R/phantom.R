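#' @include AllClasses.R utils.R registration.R
NULL

#' Specify a synthetic CT phantom pair
#'
#' The phantom emulates the paired-study setting the segmentation pipeline
#' expects: a training abdomen with a gold-standard organ mask, a target
#' abdomen generated from it by a known smooth low-frequency deformation,
#' exactly corresponding landmarks, and an intensity model designed so that
#' Gabor texture features carry boundary information. The organ is a
#' superellipsoid with a step contrast over background; a band of oriented
#' grating texture runs along the organ boundary (the statistical structure
#' the boundary dictionary learns), and the background contains a confuser
#' blob with a similar mean intensity but speckle texture to exercise
#' false-positive control.
#'
#' @param shape voxel dimensions (default 96^3).
#' @param spacing mm per voxel.
#' @param organCenter,organRadii mm; superellipsoid center and semi-axes.
#' @param organExponent superellipsoid exponent (2 = ellipsoid).
#' @param contrast organ minus background mean intensity.
#' @param noiseSigma additive Gaussian noise SD (independent per volume).
#' @param textureAmplitude,textureWavelength boundary grating intensity and
#'   period (voxels).
#' @param bandWidth half-width of the boundary texture band, voxels.
#' @param deformAmplitude mm amplitude of the true deformation.
#' @param nLandmarks landmark pairs sampled on and around the organ.
#' @param seed integer seed; the whole pair is reproducible from it.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                        organCenter = NULL, organRadii = c(30, 26, 24),
                        organExponent = 2.2, contrast = 120,
                        noiseSigma = 4, textureAmplitude = 40,
                        textureWavelength = 4, bandWidth = 2.5,
                        deformAmplitude = 4, nLandmarks = 27L, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(organCenter)) organCenter <- (shape - 1) * spacing / 2
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      organCenter = as.numeric(organCenter),
      organRadii = as.numeric(organRadii),
      organExponent = as.numeric(organExponent),
      contrast = as.numeric(contrast), noiseSigma = as.numeric(noiseSigma),
      textureAmplitude = as.numeric(textureAmplitude),
      textureWavelength = as.numeric(textureWavelength),
      bandWidth = as.numeric(bandWidth),
      deformAmplitude = as.numeric(deformAmplitude),
      nLandmarks = as.integer(nLandmarks), seed = as.integer(seed))
}

# superellipsoid implicit function on the grid (mm); <= 1 inside
organImplicit <- function(spec) {
  d <- spec@shape; sp <- spec@spacing; ctr <- spec@organCenter
  e <- spec@organExponent
  gx <- abs(((seq_len(d[1]) - 1) * sp[1] - ctr[1]) / spec@organRadii[1])^e
  gy <- abs(((seq_len(d[2]) - 1) * sp[2] - ctr[2]) / spec@organRadii[2])^e
  gz <- abs(((seq_len(d[3]) - 1) * sp[3] - ctr[3]) / spec@organRadii[3])^e
  outer(outer(gx, gy, "+"), gz, "+")
}

# smooth low-frequency deformation with seeded random phases; returns the
# (nx, ny, nz, 3) mm displacement array
trueDisplacement <- function(spec) {
  d <- spec@shape; sp <- spec@spacing
  ext <- (d - 1) * sp
  amp <- spec@deformAmplitude
  ph <- withSeed(spec@seed + 101L, stats::runif(9, 0, 2 * pi))
  gx <- (seq_len(d[1]) - 1) * sp[1]; gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  w <- 2 * pi / ext
  disp <- array(0, c(d, 3))
  ## one full period across the volume per factor: C2-smooth, zero-mean-ish
  disp[, , , 1] <- amp * outer(outer(sin(w[1] * gx + ph[1]),
                                     cos(w[2] * gy + ph[2])),
                               sin(w[3] * gz + ph[3]))
  disp[, , , 2] <- amp * outer(outer(cos(w[1] * gx + ph[4]),
                                     sin(w[2] * gy + ph[5])),
                               cos(w[3] * gz + ph[6]))
  disp[, , , 3] <- amp * outer(outer(sin(w[1] * gx + ph[7]),
                                     sin(w[2] * gy + ph[8])),
                               cos(w[3] * gz + ph[9]))
  disp
}

#' Generate a synthetic training/target phantom pair
#'
#' The target volume and mask are the training pair warped through a stored
#' smooth deformation (pull-back resampling, so the stored field is exactly
#' the field a perfect registration should recover on the target grid);
#' each volume receives independent Gaussian noise. Landmarks are placed on
#' a 3D lattice spanning the organ with exact correspondence through the
#' true field. Everything is reproducible from `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `trainingVolume`, `trainingMask`,
#'   `targetVolume`, `targetMask` (gold standards), `landmarks`
#'   ([LandmarkSet-class]) and `trueField` ([DeformationField-class]).
#' @examples
#' p <- makePhantomPair(phantomSpec(shape = c(48, 48, 48),
#'                                  organRadii = c(12, 11, 10)))
#' dim(p$trainingVolume)
#' @export
makePhantomPair <- function(spec = phantomSpec()) {
  d <- spec@shape; sp <- spec@spacing
  Fimp <- organImplicit(spec)
  organ <- Fimp <= 1
  if (!any(organ)) stop("organ is empty; check organRadii", call. = FALSE)

  base <- array(40, d)                      # soft-tissue background
  base[organ] <- 40 + spec@contrast         # organ mean

  ## boundary texture band: voxels within bandWidth (in implicit-function
  ## gradient units ~ voxels) of the F = 1 level set
  lvl <- abs(Fimp - 1)
  ## approximate voxel distance to the level set: |F-1| / |grad F| with a
  ## characteristic gradient of e/r per mm
  gradScale <- spec@organExponent / min(spec@organRadii)
  band <- lvl <= spec@bandWidth * gradScale * min(sp)
  gx <- (seq_len(d[1]) - 1) * sp[1]; gy <- (seq_len(d[2]) - 1) * sp[2]
  theta <- pi / 6                           # grating aligned with one bank angle
  phase <- 2 * pi * (outer(gx * cos(theta), gy * sin(theta), "+")) /
    (spec@textureWavelength * min(sp))
  grating <- array(rep(cos(phase), d[3]), d)
  base <- base + spec@textureAmplitude * grating * band

  ## background confuser: similar mean, different (speckle) texture
  confCtr <- spec@organCenter + c(spec@organRadii[1] + 12, 0, 0) *
    c(1, 1, 1)
  cx <- ((seq_len(d[1]) - 1) * sp[1] - confCtr[1])^2
  cy <- ((seq_len(d[2]) - 1) * sp[2] - confCtr[2])^2
  cz <- ((seq_len(d[3]) - 1) * sp[3] - confCtr[3])^2
  conf <- outer(outer(cx, cy, "+"), cz, "+") <= 8^2
  if (any(conf)) {
    base[conf] <- 40 + spec@contrast
    speck <- withSeed(spec@seed + 202L,
                      stats::rnorm(sum(conf), 0, spec@textureAmplitude))
    base[conf] <- base[conf] + speck
  }

  trainingNoise <- withSeed(spec@seed + 303L,
                            array(stats::rnorm(prod(d), 0, spec@noiseSigma), d))
  trainingVolume <- ctVolume(base + trainingNoise, sp)
  trainingMask <- ctMask(organ * 1, sp)

  disp <- trueDisplacement(spec)
  trueField <- new("DeformationField", displacement = disp, spacing = sp,
                   origin = c(0, 0, 0), controlSpacing = max((d - 1) * sp))
  if (spec@deformAmplitude > 0) {
    targetClean <- applyDeformation(trueField, ctVolume(base, sp), "linear")
    targetMask <- applyDeformation(trueField, trainingMask, "nearest")
  } else {
    targetClean <- ctVolume(base, sp)
    targetMask <- trainingMask
  }
  targetNoise <- withSeed(spec@seed + 404L,
                          array(stats::rnorm(prod(d), 0, spec@noiseSigma), d))
  targetVolume <- ctVolume(targetClean@data + targetNoise, sp)

  ## landmarks: lattice spanning the organ in target space; moving point is
  ## the pull-back position in the training image
  k <- max(2L, ceiling(spec@nLandmarks^(1 / 3)))
  axesPts <- lapply(1:3, function(a)
    seq(spec@organCenter[a] - 1.1 * spec@organRadii[a],
        spec@organCenter[a] + 1.1 * spec@organRadii[a], length.out = k))
  lat <- as.matrix(expand.grid(axesPts[[1]], axesPts[[2]], axesPts[[3]]))
  lat <- lat[seq_len(min(nrow(lat), spec@nLandmarks)), , drop = FALSE]
  fixed <- lat
  moving <- fixed + evalDeformation(trueField, fixed)
  landmarks <- landmarkSet(moving, fixed)

  list(trainingVolume = trainingVolume, trainingMask = trainingMask,
       targetVolume = targetVolume, targetMask = targetMask,
       landmarks = landmarks, trueField = trueField)
}
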