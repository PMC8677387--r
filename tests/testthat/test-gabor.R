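defaultBank <- buildGaborBank(gaborBankSpec())

gratingVolume <- function(theta, lambda, n = 32, nz = 5, amp = 50,
                          offset = 100) {
  gx <- seq_len(n) - 1
  sl <- outer(gx, gx, function(x, y)
    cos(2 * pi * (x * cos(theta) + y * sin(theta)) / lambda))
  ctVolume(array(rep(sl, nz), c(n, n, nz)) * amp + offset)
}

test_that("the default bank has 24 zero-mean unit-norm kernels", {
  expect_length(defaultBank@kernels, 24L)
  for (k in defaultBank@kernels) {
    expect_lt(abs(mean(k)), 1e-10)
    expect_equal(sum(k^2), 1, tolerance = 1e-10)
    expect_equal(dim(k), rep(2L * defaultBank@kernelRadius + 1L, 2))
  }
})

test_that("bank size follows nOrientations x nScales", {
  b1 <- buildGaborBank(gaborBankSpec(nOrientations = 1, wavelengths = 4))
  expect_length(b1@kernels, 1L)
  b2 <- buildGaborBank(gaborBankSpec(nOrientations = 9,
                                     wavelengths = c(3, 5)))
  expect_length(b2@kernels, 18L)
  expect_error(gaborBankSpec(wavelengths = c(4, 3)), "increasing")
  expect_error(gaborBankSpec(wavelengths = c(3, 20), kernelRadius = 5),
               "kernelRadius")
})

test_that("constant patches give zero features (DC rejection)", {
  v <- ctVolume(array(7, c(32, 32, 3)))
  fv <- patchFeature(v, c(16, 16, 2), c(9, 9), defaultBank)
  expect_length(fv, 24L)
  expect_lt(max(abs(fv)), 1e-10)
})

test_that("features are invariant to an intensity offset", {
  set.seed(3)
  arr <- array(rnorm(32 * 32 * 3, 0, 30), c(32, 32, 3))
  f1 <- patchFeature(ctVolume(arr), c(16, 16, 2), c(9, 9), defaultBank)
  f2 <- patchFeature(ctVolume(arr + 500), c(16, 16, 2), c(9, 9), defaultBank)
  expect_lt(max(abs(f1 - f2)), 1e-8 * max(abs(f1)))
})

test_that("a matched grating maximizes its own (orientation, scale) entry", {
  for (oi in c(1L, 3L, 5L)) for (si in c(2L, 3L)) {
    theta <- defaultBank@orientations[oi]
    lambda <- defaultBank@wavelengths[si]
    fv <- patchFeature(gratingVolume(theta, lambda), c(16, 16, 3),
                       c(9, 9), defaultBank)
    expect_equal(which.max(fv), (si - 1L) * 6L + oi)
  }
})

test_that("the argmax orientation tracks a rotating grating", {
  lambda <- defaultBank@wavelengths[2]
  for (oi in seq_along(defaultBank@orientations)) {
    fv <- patchFeature(gratingVolume(defaultBank@orientations[oi], lambda),
                       c(16, 16, 3), c(9, 9), defaultBank)
    scaleBlock <- fv[6 + 1:6]   # the lambda = wavelengths[2] block
    expect_equal(which.max(scaleBlock), oi)
  }
})

test_that("orthogonal kernels respond maximally to rotated gratings", {
  theta <- defaultBank@orientations[1]
  v0 <- gratingVolume(theta, 4)
  v90 <- gratingVolume(theta + pi / 2, 4)
  f0 <- patchFeature(v0, c(16, 16, 3), c(9, 9), defaultBank)
  f90 <- patchFeature(v90, c(16, 16, 3), c(9, 9), defaultBank)
  ## orientation 4 of 6 is theta + 90 degrees
  expect_gt(f0[6 + 1], f0[6 + 4])
  expect_gt(f90[6 + 4], f90[6 + 1])
})

test_that("translated copies of a texture give near-identical features", {
  v <- gratingVolume(defaultBank@orientations[2], 4)
  f1 <- patchFeature(v, c(16, 16, 3), c(9, 9), defaultBank)
  f2 <- patchFeature(v, c(18, 17, 3), c(9, 9), defaultBank)
  expect_lt(max(abs(f1 - f2) / pmax(abs(f1), 1e-6)), 0.05)
})

test_that("patchMatrix preserves center order and duplicates", {
  set.seed(5)
  v <- ctVolume(array(rnorm(32 * 32 * 4, 100, 20), c(32, 32, 4)))
  centers <- rbind(c(10, 10, 2), c(20, 15, 3), c(10, 10, 2))
  ps <- patchMatrix(v, centers, c(9, 9), defaultBank)
  expect_equal(nElements(ps), 3L)
  expect_equal(dim(features(ps)), c(24L, 3L))
  expect_identical(features(ps)[, 1], features(ps)[, 3])
  expect_true(all(is.finite(features(ps))))
  ## single center agrees with patchFeature
  expect_equal(features(ps)[, 2],
               patchFeature(v, c(20, 15, 3), c(9, 9), defaultBank))
  ## errors
  expect_error(patchMatrix(v, centers[0, , drop = FALSE], c(9, 9),
                           defaultBank), "empty")
  expect_error(patchFeature(v, c(2, 16, 2), c(9, 9), defaultBank), "border")
})

test_that("the feature stack agrees with direct patch features", {
  set.seed(6)
  v <- ctVolume(array(rnorm(24 * 24 * 3, 0, 10), c(24, 24, 3)))
  stack <- gaborFeatureStack(v, defaultBank, c(9, 9))
  centers <- rbind(c(8, 9, 2), c(15, 12, 1))
  direct <- patchMatrix(v, centers, c(9, 9), defaultBank)
  fromStack <- GaborDictSeg:::stackFeatures(stack, centers)
  expect_equal(fromStack, features(direct), tolerance = 1e-10)
})
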