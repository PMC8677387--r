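#' @include AllClasses.R utils.R registration.R
NULL

#' The five MICCAI 2007 segmentation metrics
#'
#' Compares a segmentation `A` against the gold standard `B` on a shared
#' grid:
#' \itemize{
#'   \item VOE = 100 (1 - |A intersect B| / |A union B|), percent;
#'   \item RVD = 100 (|A| - |B|) / |B|, percent, signed by default;
#'   \item ASSD / RMSSSD / MSSD: average, root-mean-square and maximum
#'     symmetric surface distance in mm between the 6-neighborhood surface
#'     voxel sets of A and B (voxel centers, physical spacing).
#' }
#'
#' @param A segmentation [CTMask-class].
#' @param B gold-standard [CTMask-class]; must be non-empty.
#' @param absoluteRVD report |RVD| instead of the signed value.
#' @return a [MetricsReport-class].
#' @examples
#' m <- array(0, c(12, 12, 12)); m[4:9, 4:9, 4:9] <- 1
#' computeMetrics(ctMask(m), ctMask(m))  # identical masks: all zeros
#' @export
computeMetrics <- function(A, B, absoluteRVD = FALSE) {
  stopifnot(is(A, "CTMask"), is(B, "CTMask"))
  if (!sameGrid(A, B)) stop("masks must share grid and spacing", call. = FALSE)
  a <- A@data > 0.5; b <- B@data > 0.5
  nB <- sum(b)
  if (nB == 0) stop("gold standard mask is empty (RVD undefined)",
                    call. = FALSE)
  nA <- sum(a)
  if (nA == 0) stop("segmentation mask is empty; surface distances undefined",
                    call. = FALSE)
  inter <- sum(a & b); uni <- sum(a | b)
  voe <- 100 * (1 - inter / uni)
  rvd <- 100 * (nA - nB) / nB
  if (absoluteRVD) rvd <- abs(rvd)
  SA <- voxelToPhys(boundaryCoords(extractSurfacePoints(A)), A)
  SB <- voxelToPhys(boundaryCoords(extractSurfacePoints(B)), B)
  dAB <- minCrossDist(SA, SB)
  dBA <- minCrossDist(SB, SA)
  n <- length(dAB) + length(dBA)
  assd <- (sum(dAB) + sum(dBA)) / n
  rmsssd <- sqrt((sum(dAB^2) + sum(dBA^2)) / n)
  mssd <- max(max(dAB), max(dBA))
  new("MetricsReport", voe = voe, rvd = rvd, assd = assd, rmsssd = rmsssd,
      mssd = mssd)
}

#' Aggregate per-case metric reports as mean and sample SD
#'
#' Per-dataset summaries are the arithmetic mean and the sample (n - 1)
#' standard deviation of each metric over the cases, the form in which
#' per-dataset results are conventionally reported (mean +/- SD).
#'
#' @param reports list of [MetricsReport-class] (or a numeric matrix /
#'   data.frame with columns voe, rvd, assd, rmsssd, mssd; one row per
#'   case).
#' @return data.frame with columns `metric`, `mean`, `sd` (unrounded).
#' @export
aggregateMetrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    if (length(reports) == 0) stop("empty report list", call. = FALSE)
    M <- do.call(rbind, lapply(reports, metricsVector))
  } else {
    M <- as.matrix(reports)
  }
  if (nrow(M) < 2L) stop("need at least 2 reports to aggregate",
                         call. = FALSE)
  cols <- c("voe", "rvd", "assd", "rmsssd", "mssd")
  if (!is.null(colnames(M))) M <- M[, cols, drop = FALSE]
  data.frame(metric = cols,
             mean = colMeans(M),
             sd = apply(M, 2, stats::sd),
             row.names = NULL)
}

#' Print a per-case metrics table with an Average row
#'
#' @param reports as in [aggregateMetrics()].
#' @param digits rounding for display.
#' @return invisibly, the formatted data.frame.
#' @export
formatMetricsTable <- function(reports, digits = 1) {
  if (is.list(reports) && !is.data.frame(reports))
    M <- do.call(rbind, lapply(reports, metricsVector))
  else M <- as.matrix(reports)
  agg <- aggregateMetrics(M)
  rows <- as.data.frame(round(M, 2))
  names(rows) <- c("VOE (%)", "RVD (%)", "ASSD (mm)", "RMSSSD (mm)",
                   "MSSD (mm)")
  avg <- sprintf("%.*f +/- %.*f", digits, agg$mean, digits, agg$sd)
  out <- rbind(as.data.frame(lapply(rows, as.character),
                             check.names = FALSE),
               stats::setNames(as.list(avg), names(rows)))
  rownames(out) <- c(seq_len(nrow(M)), "Average")
  print(out)
  invisible(out)
}

#' Export a metrics report to JSON or CSV
#'
#' @param report a [MetricsReport-class] or list of them.
#' @param path destination `.json` or `.csv`.
#' @return invisibly, `path`.
#' @export
writeMetrics <- function(report, path) {
  if (is(report, "MetricsReport")) report <- list(report)
  M <- do.call(rbind, lapply(report, metricsVector))
  df <- as.data.frame(M)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, digits = NA)
  else utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
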