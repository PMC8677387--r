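test_that("normalizeDictionary scales columns to unit norm", {
  D <- cbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3), c(4, 0, 0))
  nd <- normalizeDictionary(D)
  expect_equal(unname(sqrt(colSums(atoms(nd)^2))), rep(1, 4))
  ## idempotent
  nd2 <- normalizeDictionary(atoms(nd))
  expect_lt(max(abs(atoms(nd2) - atoms(nd))), 1e-12)
  ## zero column
  Dz <- D; Dz[, 2] <- 0
  expect_error(normalizeDictionary(Dz), "zero column")
  withr::with_seed(1, {
    ndz <- normalizeDictionary(Dz, replaceZero = TRUE)
    expect_equal(unname(sqrt(colSums(atoms(ndz)^2))), rep(1, 4))
  })
})

test_that("OMP recovers single atoms and orthogonal combinations exactly", {
  set.seed(11)
  D <- normalizeDictionary(matrix(rnorm(24 * 48), 24))
  fit <- omp(D, atoms(D)[, 3], T0 = 1)
  expect_equal(fit$support, 3L)
  expect_equal(fit$code[3], 1, tolerance = 1e-12)
  expect_equal(fit$residualNorm, 0, tolerance = 1e-12)

  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  Dq <- new("GaborDictionary", atoms = cbind(Q, -Q))
  y <- 2 * Q[, 1] + 3 * Q[, 2]
  f2 <- omp(Dq, y, T0 = 2)
  expect_setequal(f2$support, c(1L, 2L))
  expect_equal(sort(f2$code[f2$support]), c(2, 3), tolerance = 1e-10)
  expect_equal(f2$residualNorm, 0, tolerance = 1e-10)
  ## residual orthogonal to the selected atoms
  r <- y - atoms(Dq) %*% f2$code
  expect_lt(max(abs(crossprod(atoms(Dq)[, f2$support], r))), 1e-8)
  expect_error(omp(Dq, y, T0 = 9), "T0")
})

test_that("OMP is never beaten by the exhaustive support oracle", {
  set.seed(21)
  for (i in 1:30) {
    D <- normalizeDictionary(matrix(rnorm(60), 6))
    y <- rnorm(6)
    ro <- omp(D, y, T0 = 2)$residualNorm
    rb <- bruteOmpResidual(atoms(D), y, 2)
    expect_gte(ro, rb - 1e-10)
    expect_lte(rb, ro + 1e-10 + (ro - rb))  # oracle is the lower envelope
  }
})

test_that("reconstruction errors match an independent recomputation", {
  set.seed(31)
  D <- normalizeDictionary(matrix(rnorm(24 * 40), 24))
  ## atom -> zero error
  expect_equal(reconstructionError(D, atoms(D)[, 7], 2), 0,
               tolerance = 1e-10)
  ## orthogonal complement of an orthonormal sub-dictionary -> ||y||
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  Dsub <- new("GaborDictionary", atoms = cbind(Q[, 1:3], -Q[, 1:3], Q[, 1:2]))
  y <- Q[, 5]
  expect_equal(reconstructionError(Dsub, y, 3), sqrt(sum(y^2)),
               tolerance = 1e-10)
  ## random case: recompute the residual from the returned code
  y2 <- rnorm(24)
  fit <- omp(D, y2, T0 = 4)
  expect_equal(reconstructionError(D, y2, 4),
               sqrt(sum((y2 - atoms(D) %*% fit$code)^2)), tolerance = 1e-10)
  ## L(y) <= ||y|| always (x = 0 is feasible)
  for (i in 1:20) {
    y3 <- rnorm(24) * 10^runif(1, -3, 3)
    expect_lte(reconstructionError(D, y3, 4), sqrt(sum(y3^2)) + 1e-12)
  }
  expect_error(reconstructionError(D, rnorm(10), 2), "dimension")
})

test_that("K-SVD collapses rank-1 data onto one atom", {
  set.seed(41)
  u <- rnorm(8); u <- u / sqrt(sum(u^2))
  Y <- matrix(rep(u, 50), 8)
  fit <- suppressWarnings(
    ksvdTrain(Y, ksvdConfig(t = 9, T0 = 1, nIterations = 5, seed = 3)))
  expect_lt(utils::tail(fit$objective, 1), 1e-10)
  sims <- abs(crossprod(atoms(fit$dictionary), u))
  expect_gt(max(sims), 1 - 1e-8)
})

test_that("K-SVD maintains its invariants on seeded synthetic data", {
  set.seed(51)
  m <- 12; t <- 18; N <- 120
  Dt <- normalizeDictionary(matrix(rnorm(m * t), m))
  X <- matrix(0, t, N)
  for (i in seq_len(N)) X[sample(t, 2), i] <- runif(2, 0.5, 2)
  Y <- atoms(Dt) %*% X + matrix(rnorm(m * N, 0, 0.01), m)
  fit <- ksvdTrain(Y, ksvdConfig(t = t, T0 = 2, nIterations = 15, seed = 9))
  ## objective monotone non-increasing
  expect_true(all(diff(fit$objective) <= 1e-9))
  ## unit-norm atoms after training
  expect_equal(unname(sqrt(colSums(atoms(fit$dictionary)^2))), rep(1, t),
               tolerance = 1e-10)
  ## every code column obeys the sparsity bound
  expect_true(all(colSums(codes(fit$codes) != 0) <= 2))
  ## more iterations never hurt
  fit1 <- ksvdTrain(Y, ksvdConfig(t = t, T0 = 2, nIterations = 1, seed = 9))
  expect_lte(utils::tail(fit$objective, 1), fit1$objective[1] + 1e-9)
  expect_error(ksvdTrain(matrix(0, 4, 10), ksvdConfig(t = 6, T0 = 1)),
               "all-zero")
})

test_that("dictionaries persist through JSON round trip", {
  set.seed(61)
  Y <- matrix(rnorm(12 * 80), 12)
  fit <- ksvdTrain(Y, ksvdConfig(t = 16, T0 = 2, nIterations = 3, seed = 2))
  f <- tempfile(fileext = ".json")
  writeDictionary(fit, f)
  back <- readDictionary(f)
  expect_lt(max(abs(atoms(back$dictionary) - atoms(fit$dictionary))), 1e-12)
  expect_lt(max(abs(codes(back$codes) - codes(fit$codes))), 1e-12)
})
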