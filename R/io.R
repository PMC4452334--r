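# Image/sinogram I/O: NPY (lossless doubles, any range) or 32-bit TIFF
# (display-window container, values clipped to [0, 1] on write); YAML for
# geometry configs, CSV for profiles and iteration logs.

#' Write an image or sinogram to NPY or TIFF
#'
#' The container is chosen from the file extension. `.npy` stores the matrix
#' losslessly as little-endian float64 in C order ([write_npy()]) and is the
#' right choice for sinograms and any data leaving \[0, 1\]. `.tif`/`.tiff`
#' writes an uncompressed single-page 32-bit TIFF via the `tiff` package,
#' which quantizes to the \[0, 1\] display window (out-of-range values are
#' clipped, with a warning).
#'
#' @param x numeric matrix.
#' @param path output file ending in `.npy`, `.tif` or `.tiff`.
#' @export
write_image <- function(x, path) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) return(write_npy(x, path))
  if (any(x < 0) || any(x > 1)) {
    warning("values outside [0, 1] are clipped by the TIFF container; use .npy for lossless storage")
    x <- pmin(pmax(x, 0), 1)
  }
  tiff::writeTIFF(x, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @param geometry optional [scan_geometry()] to attach (for sinograms).
#' @return `read_image` returns the numeric matrix.
#' @export
read_image <- function(path, geometry = NULL) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    x <- read_npy(path)
  } else {
    x <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(x)) == 3L) x <- x[, , 1]
  }
  if (!is.null(geometry)) attr(x, "geometry") <- geometry
  x
}

#' Minimal NPY (v1.0) container for 2-D numeric arrays
#'
#' Stores an R matrix as a little-endian, C-order float64 NPY file and reads
#' such files back (float32 input is also accepted on read). No installed R
#' package provides this container, and the TIFF package cannot hold values
#' outside \[0, 1\] losslessly, so this is written by hand.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @export
write_npy <- function(x, path) {
  if (!is.matrix(x)) stop("x must be a matrix")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(x), ncol(x))
  pad <- 64L - (10L + nchar(header) + 1L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(x)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @return `read_npy` returns the numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file")
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  if (!descr %in% c("<f8", "<f4")) stop("unsupported NPY dtype: ", descr)
  if (grepl("'fortran_order':\\s*True", header)) stop("Fortran-order NPY not supported")
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  if (length(dims) != 2L) stop("only 2-D NPY arrays are supported")
  sz <- if (descr == "<f8") 8L else 4L
  vals <- readBin(con, "double", prod(dims), size = sz, endian = "little")
  matrix(vals, dims[1], dims[2], byrow = TRUE)
}

#' Write / read a scan geometry config (YAML)
#'
#' Keys: `n_views`, `angular_range_deg`, `angular_interval_deg`,
#' `n_detector`, `detector_spacing`.
#'
#' @param geometry a [scan_geometry()].
#' @param path file path.
#' @export
write_geometry <- function(geometry, path) {
  yaml::write_yaml(geometry[c("n_views", "angular_range_deg",
                              "angular_interval_deg", "n_detector",
                              "detector_spacing")], path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- yaml::read_yaml(path)
  scan_geometry(n_views = g$n_views, angular_range_deg = g$angular_range_deg,
                angular_interval_deg = g$angular_interval_deg,
                n_detector = g$n_detector,
                detector_spacing = g$detector_spacing %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a line-profile CSV
#'
#' Columns: `column`, one value column per named profile.
#'
#' @param profiles named list of equal-length numeric vectors.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(column = seq_along(profiles[[1]]))
  for (nm in names(profiles)) df[[nm]] <- profiles[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an iteration log as CSV (sweep, residual, mse)
#'
#' @param log the `log` element of a [reconstruct()] result.
#' @param path output file.
#' @export
write_iteration_log <- function(log, path) {
  utils::write.csv(log[c("sweep", "residual", "mse")], path, row.names = FALSE)
  invisible(path)
}
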