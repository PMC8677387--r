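#' @include AllClasses.R utils.R
NULL

## NIfTI via RNifti; MetaImage (.mhd/.mha) via a minimal reader/writer for the
## plain text-header + raw-data format (no R package on the system reads it).

niftiExt <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
mhdExt   <- function(path) grepl("\\.mhd$", path, ignore.case = TRUE)
mhaExt   <- function(path) grepl("\\.mha$", path, ignore.case = TRUE)

#' Read a 3D volume or mask
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) and MetaImage
#' (`.mhd` + `.raw`, or single-file `.mha`). Spacing and origin are taken
#' from the header; a file without positive spacing is rejected rather than
#' silently defaulting to 1 mm. Volumes are axis-aligned (no direction
#' cosines); an oblique NIfTI rotation is rejected.
#'
#' @param path file to read.
#' @param mask if TRUE, validate as binary and return a [CTMask-class].
#' @return a [CTVolume-class] (or [CTMask-class]).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ctVolume(array(0, c(4, 4, 4)), spacing = c(0.7, 0.7, 2.5)), f)
#' readVolume(f)
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (niftiExt(path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
    if (length(dim(img)) != 3L)
      stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
           call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    rot <- xf[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)), 1)))
      stop("oblique/rotated volumes are not supported: ", path, call. = FALSE)
    org <- xf[1:3, 4]
    dat <- array(as.numeric(img), dim(img))
  } else if (mhdExt(path) || mhaExt(path)) {
    parsed <- readMetaImage(path)
    dat <- parsed$data; sp <- parsed$spacing; org <- parsed$origin
  } else {
    stop("unsupported volume format (need .nii/.nii.gz/.mhd/.mha): ", path,
         call. = FALSE)
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or non-positive voxel spacing in header: ", path,
         call. = FALSE)
  if (any(!is.finite(dat)))
    stop("volume contains NaN/Inf voxels: ", path, call. = FALSE)
  if (mask) ctMask(dat, sp, org) else ctVolume(dat, sp, org)
}

#' Write a 3D volume or mask
#'
#' Masks are stored as uint8 (bit-identical round trip); volumes as float64.
#'
#' @param v a [CTVolume-class] or [CTMask-class].
#' @param path destination; format chosen by extension
#'   (`.nii`/`.nii.gz`/`.mhd`/`.mha`).
#' @return invisibly, `path`.
#' @export
writeVolume <- function(v, path) {
  stopIfNot3d(v)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir,
                             call. = FALSE)
  isMask <- is(v, "CTMask")
  if (niftiExt(path)) {
    img <- RNifti::asNifti(v@data)
    xf <- structure(diag(c(v@spacing, 1)), code = 2L)
    xf[1:3, 4] <- v@origin
    img <- RNifti::`qform<-`(img, value = xf)
    img <- RNifti::`pixdim<-`(img, value = v@spacing)
    tryCatch(RNifti::writeNifti(img, path,
                                datatype = if (isMask) "uint8" else "double"),
             error = function(e) stop("failed to write ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  } else if (mhdExt(path) || mhaExt(path)) {
    writeMetaImage(v, path, isMask)
  } else {
    stop("unsupported volume format (need .nii/.nii.gz/.mhd/.mha): ", path,
         call. = FALSE)
  }
  invisible(path)
}

# --- MetaImage -------------------------------------------------------------

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path,
                                 call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line,
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3"))
    stop("only 3D MetaImage volumes are supported: ", path, call. = FALSE)
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (is.null(hdr[["ElementSpacing"]]))
    stop("missing ElementSpacing in MetaImage header: ", path, call. = FALSE)
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  org <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  n <- prod(d)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(toupper(datafile), "LOCAL")) {
    raw <- readElements(con, type, n)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("missing raw data file: ", rawpath,
                                    call. = FALSE)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readElements(con2, type, n)
  }
  list(data = array(raw, d), spacing = sp, origin = org)
}

readElements <- function(con, type, n) {
  switch(type,
    MET_UCHAR  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                    endian = "little")),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported MetaImage ElementType: ", type, call. = FALSE))
}

writeMetaImage <- function(v, path, isMask) {
  d <- dim(v@data)
  type <- if (isMask) "MET_UCHAR" else "MET_DOUBLE"
  single <- mhaExt(path)
  datafile <- if (single) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)),
                                              ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(format(v@spacing, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(v@origin, digits = 17), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeData <- function(cc) {
    if (isMask) writeBin(as.integer(v@data), cc, size = 1)
    else writeBin(as.numeric(v@data), cc, size = 8, endian = "little")
  }
  if (single) writeData(con)
  else {
    con2 <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con2), add = TRUE)
    writeData(con2)
  }
  invisible(path)
}

#' Read paired landmarks from CSV
#'
#' One row per pair, 6 numeric columns `mx,my,mz,fx,fy,fz` in physical mm
#' (moving/training point first, fixed/target point second). A header row is
#' optional. At least 4 pairs are required so the deformation fit is
#' solvable.
#'
#' @param path CSV file.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  ## a header row is all column names; a partly numeric first row is data
  hasHeader <- all(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(df) != 6L)
    stop("landmark CSV must have 6 columns (mx,my,mz,fx,fy,fz), got ",
         ncol(df), call. = FALSE)
  m <- suppressWarnings(apply(df, 2, as.numeric))
  m <- matrix(m, ncol = 6)
  if (anyNA(m)) stop("non-numeric field in landmark CSV: ", path, call. = FALSE)
  if (nrow(m) < 4L)
    stop("at least 4 landmark pairs are required, got ", nrow(m), call. = FALSE)
  landmarkSet(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Write landmarks to CSV
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path destination CSV.
#' @return invisibly, `path`.
#' @export
writeLandmarks <- function(landmarks, path) {
  df <- cbind(as.data.frame(landmarks@moving), as.data.frame(landmarks@fixed))
  names(df) <- c("mx", "my", "mz", "fx", "fy", "fz")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
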