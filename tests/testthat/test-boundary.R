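test_that("training patches are drawn from the gold boundary, seeded", {
  ## single eligible center
  a <- array(0, c(32, 32, 5)); a[16, 16, 3] <- 1
  v <- ctVolume(array(rnorm(32 * 32 * 5), c(32, 32, 5)))
  bank <- buildGaborBank(gaborBankSpec())
  ps <- sampleTrainingPatches(v, ctMask(a), c(9, 9), 1, seed = 1, bank = bank)
  expect_equal(patchCenters(ps), matrix(c(16L, 16L, 3L), 1),
               ignore_attr = TRUE)
  ## too few eligible centers
  expect_error(sampleTrainingPatches(v, ctMask(a), c(9, 9), 5, seed = 1,
                                     bank = bank), "eligible")
  ## determinism and surface membership on a ball
  d <- c(40, 40, 16)
  ball <- makeBallArray(d, c(20, 20, 8), 6)
  vb <- ctVolume(array(rnorm(prod(d), 100, 20), d))
  p1 <- sampleTrainingPatches(vb, ctMask(ball), c(9, 9), 50, seed = 7,
                              bank = bank)
  p2 <- sampleTrainingPatches(vb, ctMask(ball), c(9, 9), 50, seed = 7,
                              bank = bank)
  expect_identical(features(p1), features(p2))
  expect_identical(patchCenters(p1), patchCenters(p2))
  surf <- boundaryCoords(extractSurfacePoints(ctMask(ball)))
  keys <- paste(surf[, 1], surf[, 2], surf[, 3])
  expect_true(all(paste(patchCenters(p1)[, 1], patchCenters(p1)[, 2],
                        patchCenters(p1)[, 3]) %in% keys))
  expect_equal(anyDuplicated(patchCenters(p1)), 0L)
})

test_that("candidate neighborhoods follow the 10-per-axis rule", {
  ctrV <- boundaryPoints(matrix(c(10L, 10L, 10L), 1))
  cs <- candidateCenters(ctrV, 5, c(20, 20, 20))
  expect_equal(nrow(cs@candidates), 30L)
  expect_equal(anyDuplicated(cs@candidates), 0L)
  ## every candidate differs from the vertex along exactly one axis
  diffs <- sweep(cs@candidates, 2, c(10L, 10L, 10L))
  expect_true(all(rowSums(diffs != 0) == 1))
  expect_true(all(abs(diffs[diffs != 0]) <= 5))
  ## corner vertex: out-of-bounds candidates clipped
  corner <- boundaryPoints(matrix(c(1L, 1L, 1L), 1))
  expect_equal(nrow(candidateCenters(corner, 5, c(20, 20, 20))@candidates),
               15L)
  ## radius 1 gives the 6 face neighbors
  expect_equal(nrow(candidateCenters(ctrV, 1, c(20, 20, 20))@candidates), 6L)
  expect_error(candidateCenters(ctrV, 0, c(20, 20, 20)), "radius")
})

test_that("the zero-error candidate wins the per-vertex argmin", {
  set.seed(9)
  d <- c(40, 40, 7)
  v <- ctVolume(array(rnorm(prod(d), 0, 25), d))
  bank <- buildGaborBank(gaborBankSpec())
  vertex <- boundaryPoints(matrix(c(20L, 20L, 4L), 1))
  cs <- candidateCenters(vertex, 2, d)
  ## dictionary containing the exact feature of one candidate
  star <- c(22L, 20L, 4L)
  fstar <- patchFeature(v, star, c(9, 9), bank)
  D <- normalizeDictionary(cbind(fstar, matrix(rnorm(24 * 30), 24)))
  sel <- selectBoundaryPoints(cs, v, c(9, 9), D, T0 = 1, bank = bank,
                              normalizeFeatures = FALSE)
  expect_equal(boundaryCoords(sel), matrix(star, 1), ignore_attr = TRUE)
})

test_that("exact ties break to the lowest (z, y, x) center", {
  d <- c(30, 30, 9)
  v <- ctVolume(array(5, d))     # constant: every feature is zero
  bank <- buildGaborBank(gaborBankSpec())
  vertex <- boundaryPoints(matrix(c(15L, 15L, 5L), 1))
  cs <- candidateCenters(vertex, 1, d)
  D <- normalizeDictionary(matrix(rnorm(24 * 30), 24))
  sel <- selectBoundaryPoints(cs, v, c(9, 9), D, T0 = 1, bank = bank,
                              normalizeFeatures = FALSE)
  ## all six candidates have error 0; (15, 15, 4) has the lowest z
  expect_equal(boundaryCoords(sel), matrix(c(15L, 15L, 4L), 1),
               ignore_attr = TRUE)
})

test_that("selection stays inside the candidate set and deduplicates", {
  set.seed(13)
  d <- c(40, 40, 11)
  v <- ctVolume(array(rnorm(prod(d), 0, 25), d))
  bank <- buildGaborBank(gaborBankSpec())
  verts <- boundaryPoints(cbind(c(18L, 19L, 20L), c(18L, 18L, 18L),
                                c(6L, 6L, 6L)))
  cs <- candidateCenters(verts, 3, d)
  D <- normalizeDictionary(matrix(rnorm(24 * 30), 24))
  sel <- selectBoundaryPoints(cs, v, c(9, 9), D, T0 = 2, bank = bank)
  selKeys <- paste(boundaryCoords(sel)[, 1], boundaryCoords(sel)[, 2],
                   boundaryCoords(sel)[, 3])
  candKeys <- paste(cs@candidates[, 1], cs@candidates[, 2],
                    cs@candidates[, 3])
  expect_true(all(selKeys %in% candKeys))
  expect_equal(anyDuplicated(selKeys), 0L)
  expect_lte(nElements(sel), 3L)
  ## border-crossing candidates are dropped with a message
  edge <- boundaryPoints(matrix(c(5L, 20L, 6L), 1))
  cse <- candidateCenters(edge, 3, d)
  expect_message(selectBoundaryPoints(cse, v, c(9, 9), D, 2, bank = bank),
                 "dropped")
})

test_that("dictionary selection beats a random-candidate baseline", {
  spec <- smallPhantomSpec(seed = 4L)
  p <- makePhantomPair(spec)
  bank <- buildGaborBank(gaborBankSpec())
  ## prior = gold boundary of the training volume segmenting itself
  prior <- extractSurfacePoints(p$trainingMask)
  cands <- candidateCenters(prior, 5, dim(p$trainingVolume))
  train <- sampleTrainingPatches(p$trainingVolume, p$trainingMask, c(9, 9),
                                 400, seed = 3, bank = bank)
  fit <- ksvdTrain(train, ksvdConfig(t = 48, T0 = 2, seed = 5))
  sel <- selectBoundaryPoints(cands, p$trainingVolume, c(9, 9),
                              fit$dictionary, 2, bank = bank)
  gold <- boundaryCoords(prior)
  dSel <- GaborDictSeg:::minCrossDist(boundaryCoords(sel), gold)
  ## random baseline: one uniformly drawn candidate per vertex
  rnd <- withr::with_seed(8, {
    pick <- vapply(split(seq_len(nrow(cands@candidates)), cands@vertex),
                   function(ix) ix[sample.int(length(ix), 1)], integer(1))
    cands@candidates[pick, , drop = FALSE]
  })
  dRnd <- GaborDictSeg:::minCrossDist(rnd, gold)
  expect_lt(mean(dSel), mean(dRnd))
})
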