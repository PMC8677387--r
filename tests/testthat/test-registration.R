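targetGrid <- function(n = 24) ctVolume(array(0, c(n, n, n)))

test_that("identity landmarks give a zero field", {
  pts <- matrix(runif(15, 4, 18), 5)
  f <- fitLandmarkDeformation(landmarkSet(pts, pts), targetGrid())
  expect_equal(max(abs(f@displacement)), 0, tolerance = 1e-10)
})

test_that("a pure translation reproduces as a constant field", {
  pts <- matrix(runif(15, 4, 18), 5)
  shift <- c(3, 0, 0)
  lm <- landmarkSet(sweep(pts, 2, shift, "+"), pts)
  f <- fitLandmarkDeformation(lm, targetGrid(), regularizationWeight = 0)
  for (comp in 1:3)
    expect_equal(range(f@displacement[, , , comp]),
                 rep(shift[comp], 2), tolerance = 1e-8)
})

test_that("the field interpolates every landmark within 0.5 voxel", {
  set.seed(7)
  for (rep in 1:3) {
    pts <- matrix(runif(24, 3, 20), 8)
    mov <- pts + matrix(rnorm(24, 0, 2), 8)
    lm <- landmarkSet(mov, pts)
    f <- fitLandmarkDeformation(lm, targetGrid(), controlSpacing = 8,
                                regularizationWeight = 0)
    err <- evalDeformation(f, pts) - (mov - pts)
    expect_lt(max(abs(err)), 0.5)
  }
})

test_that("a known smooth field is recovered from landmark samples", {
  spec <- smallPhantomSpec()
  p <- makePhantomPair(spec)
  f <- fitLandmarkDeformation(p$landmarks, p$targetVolume,
                              controlSpacing = 24)
  ## compare over the organ region (where landmarks live)
  organ <- which(imgData(p$targetMask) > 0.5, arr.ind = TRUE)
  sub <- organ[seq(1, nrow(organ), by = 23), , drop = FALSE]
  pts <- voxelToPhys(sub, p$targetVolume)
  err <- evalDeformation(f, pts) - evalDeformation(p$trueField, pts)
  meanErr <- mean(sqrt(rowSums(err^2)))
  expect_lt(meanErr, 1)  # < 1 voxel at 1 mm spacing
})

test_that("degenerate coplanar landmarks fall back with a warning", {
  pts <- cbind(matrix(runif(10, 4, 18), 5), 8)   # all in z = 8 plane
  mov <- pts + cbind(0, 0, c(1, -1, 1, -1, 1))   # inconsistent normal shifts
  expect_warning(
    fitLandmarkDeformation(landmarkSet(mov, pts), targetGrid()),
    "degenerate")
})

test_that("warping preserves identity, shifts, and binarity", {
  n <- 24
  zero <- new("DeformationField",
              displacement = array(0, c(n, n, n, 3)),
              spacing = c(1, 1, 1), origin = c(0, 0, 0), controlSpacing = 8)
  v <- ctVolume(array(rnorm(n^3), c(n, n, n)))
  expect_equal(imgData(applyDeformation(zero, v, "linear")), imgData(v))

  ball <- ctMask(makeBallArray(c(n, n, n), c(12, 12, 12), 5))
  shift <- zero
  shift@displacement[, , , 1] <- 3   # pull-back +3 mm => content moves -3
  w <- applyDeformation(shift, ball, "nearest")
  expect_identical(sum(imgData(w)), sum(imgData(ball)))
  expect_true(all(unique(as.vector(imgData(w))) %in% c(0, 1)))
  cw <- colMeans(which(imgData(w) == 1, arr.ind = TRUE))
  cb <- colMeans(which(imgData(ball) == 1, arr.ind = TRUE))
  expect_equal(cw - cb, c(-3, 0, 0), ignore_attr = TRUE)

  expect_error(applyDeformation(zero, ball, "linear"), "binarity")
})

test_that("warped phantom gold overlaps the true target gold", {
  p <- makePhantomPair(smallPhantomSpec())
  f <- fitLandmarkDeformation(p$landmarks, p$targetVolume)
  warped <- applyDeformation(f, p$trainingMask, "nearest")
  expect_lt(voeOf(warped, p$targetMask), 15)
})

test_that("surface extraction matches the 6-neighbor definition", {
  ## single voxel
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  s <- extractSurfacePoints(ctMask(a))
  expect_equal(boundaryCoords(s), matrix(c(3L, 3L, 3L), 1))
  ## solid cube: 5^3 - 3^3 = 98, equals the brute-force scan
  cube <- makeCubeArray(c(7, 7, 7), c(2, 2, 2), c(6, 6, 6))
  s2 <- extractSurfacePoints(ctMask(cube))
  expect_equal(nElements(s2), 98L)
  br <- bruteSurface(cube)
  expect_equal(nrow(br), 98L)
  expect_setequal(paste(boundaryCoords(s2)[, 1], boundaryCoords(s2)[, 2],
                        boundaryCoords(s2)[, 3]),
                  paste(br[, 1], br[, 2], br[, 3]))
  ## full-volume mask: boundary is the outer shell
  full <- array(1, c(4, 4, 4))
  expect_equal(nElements(extractSurfacePoints(ctMask(full))), 64L - 8L)
  ## empty mask errors; removing the surface strictly shrinks the mask
  expect_error(extractSurfacePoints(ctMask(array(0, c(3, 3, 3)))), "empty")
  ball <- makeBallArray(c(16, 16, 16), c(8, 8, 8), 5)
  sb <- boundaryCoords(extractSurfacePoints(ctMask(ball)))
  expect_true(all(ball[sb] == 1))
  inner <- ball; inner[sb] <- 0
  expect_lt(sum(inner), sum(ball))
})

test_that("deformation fields serialize to 4-channel NIfTI", {
  n <- 8
  f <- new("DeformationField",
           displacement = array(rnorm(n^3 * 3), c(n, n, n, 3)),
           spacing = c(1, 1, 2), origin = c(0, -5, 3), controlSpacing = 8)
  path <- tempfile(fileext = ".nii.gz")
  writeDeformationField(f, path)
  b <- readDeformationField(path, controlSpacing = 8)
  expect_lt(max(abs(b@displacement - f@displacement)), 1e-6)
  expect_equal(b@spacing, f@spacing, tolerance = 1e-6)
})
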