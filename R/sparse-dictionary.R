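#' @include AllClasses.R utils.R
NULL

#' K-SVD training configuration
#'
#' Defaults are standard K-SVD practice for 24-dimensional features: 64
#' atoms, sparsity 4, 30 alternations.
#'
#' @param t atom count (dictionary columns); must exceed the feature length
#'   for an overcomplete dictionary.
#' @param T0 sparsity bound (L0) per code column.
#' @param nIterations maximum alternations.
#' @param seed integer seed for the random initialization.
#' @param replaceUnusedAtoms replace atoms never selected during a sparse
#'   coding pass with the worst-reconstructed training sample.
#' @return a [KSVDConfig-class].
#' @export
ksvdConfig <- function(t = 64L, T0 = 4L, nIterations = 30L, seed = 1L,
                       replaceUnusedAtoms = TRUE) {
  new("KSVDConfig", t = as.integer(t), T0 = as.integer(T0),
      nIterations = as.integer(nIterations), seed = as.integer(seed),
      replaceUnusedAtoms = isTRUE(replaceUnusedAtoms))
}

#' Normalize dictionary columns to unit L2 norm
#'
#' @param D m x t numeric matrix with m < t.
#' @param replaceZero if TRUE, a zero column is replaced by a random unit
#'   vector (uses the current RNG state); otherwise a zero column is an
#'   error.
#' @return a [GaborDictionary-class].
#' @export
normalizeDictionary <- function(D, replaceZero = FALSE) {
  D <- as.matrix(D)
  nrm <- sqrt(colSums(D^2))
  zero <- nrm < 1e-300
  if (any(zero)) {
    if (!replaceZero)
      stop(sum(zero), " zero column(s) in dictionary", call. = FALSE)
    for (j in which(zero)) {
      v <- stats::rnorm(nrow(D))
      D[, j] <- v
    }
    nrm <- sqrt(colSums(D^2))
  }
  new("GaborDictionary", atoms = sweep(D, 2, nrm, "/"))
}

#' Orthogonal matching pursuit for one signal
#'
#' Greedy sparse coding: each step selects the atom with the largest
#' absolute correlation with the current residual (ties broken by lowest
#' atom index), then re-solves the coefficients by least squares on the
#' selected support, leaving the residual orthogonal to all selected atoms.
#' Stops after `T0` atoms or when the residual norm drops to `residualTol`.
#'
#' @param D a [GaborDictionary-class].
#' @param y numeric signal of length `nrow(atoms(D))`.
#' @param T0 sparsity bound; must not exceed the atom count.
#' @param residualTol early-exit residual norm.
#' @return list with `code` (length-t sparse coefficient vector),
#'   `support` (selected atom indices) and `residualNorm`.
#' @examples
#' D <- normalizeDictionary(matrix(rnorm(24 * 48), 24))
#' fit <- omp(D, atoms(D)[, 3], T0 = 1)
#' fit$support  # 3
#' @export
omp <- function(D, y, T0, residualTol = 0) {
  stopifnot(is(D, "GaborDictionary"))
  A <- D@atoms
  if (length(y) != nrow(A))
    stop("signal length ", length(y), " does not match feature dimension ",
         nrow(A), call. = FALSE)
  if (T0 > ncol(A)) stop("T0 exceeds the atom count", call. = FALSE)
  res <- .ompBatchCpp(A, matrix(as.numeric(y), ncol = 1), as.integer(T0),
                      as.numeric(residualTol))
  code <- res$codes[, 1]
  list(code = code, support = which(code != 0), residualNorm = res$residuals[1])
}

# batch sparse coding: Y is m x N; returns list(codes = t x N, residuals)
ompBatch <- function(D, Y, T0, residualTol = 0) {
  .ompBatchCpp(D@atoms, Y, as.integer(T0), as.numeric(residualTol))
}

#' Sparse reconstruction error of a signal under a dictionary
#'
#' The residual norm `||y - D x||` of the best `T0`-sparse OMP approximation
#' — the patch score used to pick liver-boundary patches (low error means
#' the patch looks like the boundary patches the dictionary was trained on).
#'
#' @inheritParams omp
#' @return non-negative scalar.
#' @export
reconstructionError <- function(D, y, T0, residualTol = 0) {
  stopifnot(is(D, "GaborDictionary"))
  if (length(y) != nrow(D@atoms))
    stop("signal length does not match dictionary feature dimension",
         call. = FALSE)
  as.numeric(.reconErrorsCpp(D@atoms, matrix(as.numeric(y), ncol = 1),
                             as.integer(T0), as.numeric(residualTol)))
}

#' Batch reconstruction errors
#'
#' @param D a [GaborDictionary-class].
#' @param Y m x N matrix of signals (columns).
#' @param T0 sparsity bound.
#' @param residualTol early-exit residual norm.
#' @return numeric(N) of residual norms.
#' @export
reconstructionErrors <- function(D, Y, T0, residualTol = 0) {
  stopifnot(is(D, "GaborDictionary"))
  as.numeric(.reconErrorsCpp(D@atoms, as.matrix(Y), as.integer(T0),
                             as.numeric(residualTol)))
}

#' Train a dictionary by K-SVD
#'
#' Alternates (a) OMP sparse coding of every training column and (b)
#' per-atom updates by rank-1 SVD of the residual matrix restricted to the
#' samples that use the atom. If a fresh OMP code for a column is worse than
#' the column's previous (equally sparse) code, the previous code is kept,
#' so the objective `||Y - D X||_F^2` is non-increasing across iterations.
#' Unused atoms are optionally replaced by the worst-reconstructed sample.
#' Initialization draws `t` distinct training columns (seeded).
#'
#' @param Y m x N training matrix (or a [PatchSet-class]).
#' @param config a [KSVDConfig-class].
#' @param relTol stop when the relative objective decrease falls below this.
#' @return list with `dictionary` ([GaborDictionary-class]), `codes`
#'   ([SparseCodes-class]) and `objective` (per-iteration values).
#' @export
ksvdTrain <- function(Y, config = ksvdConfig(), relTol = 1e-6) {
  if (is(Y, "PatchSet")) Y <- Y@features
  Y <- as.matrix(Y)
  m <- nrow(Y); N <- ncol(Y)
  if (all(Y == 0)) stop("all-zero training matrix", call. = FALSE)
  t <- config@t; T0 <- config@T0
  if (T0 > m) stop("T0 must not exceed the feature length", call. = FALSE)
  if (m >= t) stop("dictionary must be overcomplete: need t > m", call. = FALSE)
  if (N < t) warning("fewer training samples (", N, ") than atoms (", t,
                     ")", call. = FALSE)

  D <- withSeed(config@seed, {
    nrm <- sqrt(colSums(Y^2))
    eligible <- which(nrm > 1e-12)
    init <- if (length(eligible) >= t) sample(eligible, t)
            else sample(N, t, replace = TRUE)
    D0 <- Y[, init, drop = FALSE]
    ## perturb duplicates/zeros so normalization is defined
    bad <- sqrt(colSums(D0^2)) < 1e-12
    if (any(bad)) D0[, bad] <- matrix(stats::rnorm(m * sum(bad)), m)
    normalizeDictionary(D0)@atoms
  })

  X <- matrix(0, t, N)
  prevResid2 <- rep(Inf, N)
  objective <- numeric(0)
  for (iter in seq_len(config@nIterations)) {
    ## (a) sparse coding, keeping any previous code that is still better
    sc <- .ompBatchCpp(D, Y, T0, 0)
    newResid2 <- sc$residuals^2
    curResid2 <- colSums((Y - D %*% X)^2)
    worse <- newResid2 > curResid2 + 1e-12
    X <- sc$codes
    if (iter > 1L && any(worse)) {
      ## recover the old columns (cheap: only the few affected)
      X[, worse] <- Xprev[, worse]
      newResid2[worse] <- curResid2[worse]
    }
    ## (b) atom-by-atom update
    R <- Y - D %*% X
    for (k in seq_len(t)) {
      users <- which(X[k, ] != 0)
      if (length(users) == 0L) {
        if (config@replaceUnusedAtoms) {
          resid2 <- colSums(R^2)
          w <- which.max(resid2)
          if (resid2[w] > 1e-20) {
            D[, k] <- Y[, w] / sqrt(sum(Y[, w]^2))
          }
        }
        next
      }
      ## restricted error matrix: add this atom's contribution back
      Ek <- R[, users, drop = FALSE] +
        D[, k, drop = FALSE] %*% X[k, users, drop = FALSE]
      sv <- svd(Ek, nu = 1, nv = 1)
      dNew <- sv$u[, 1]
      ## deterministic sign: largest-magnitude entry positive
      s <- sign(dNew[which.max(abs(dNew))]); if (s == 0) s <- 1
      dNew <- dNew * s
      xNew <- sv$d[1] * sv$v[, 1] * s
      R[, users] <- Ek - dNew %*% t(xNew)
      D[, k] <- dNew
      X[k, users] <- xNew
    }
    obj <- sum(R^2)
    objective <- c(objective, obj)
    Xprev <- X
    if (iter > 1L) {
      prev <- objective[iter - 1L]
      if (prev > 0 && (prev - obj) / prev < relTol) break
    }
  }
  list(dictionary = new("GaborDictionary", atoms = D),
       codes = new("SparseCodes", codes = X, sparsity = T0),
       objective = objective)
}

#' Persist a dictionary (and optionally its codes) to JSON
#'
#' @param fit result of [ksvdTrain()], or a [GaborDictionary-class].
#' @param path destination `.json`.
#' @return invisibly, `path`.
#' @export
writeDictionary <- function(fit, path) {
  if (is(fit, "GaborDictionary")) fit <- list(dictionary = fit)
  obj <- list(atoms = fit$dictionary@atoms)
  if (!is.null(fit$codes)) {
    obj$codes <- fit$codes@codes
    obj$sparsity <- fit$codes@sparsity
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a dictionary written by [writeDictionary()]
#'
#' @param path `.json` file.
#' @return list with `dictionary` and, if stored, `codes`.
#' @export
readDictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(dictionary = new("GaborDictionary", atoms = as.matrix(obj$atoms)))
  if (!is.null(obj$codes))
    out$codes <- new("SparseCodes", codes = as.matrix(obj$codes),
                     sparsity = as.integer(obj$sparsity))
  out
}
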