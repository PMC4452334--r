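#' Linearly partial-derivative projection operator
#'
#' Builds the sparse matrix `B` mapping a refraction-index-decrement image to
#' its differential (refraction-angle) projections: each ray's row realizes
#' the line integral of the image derivative transverse to the ray. It is
#' discretized as a Joseph-style interpolated line integral composed with a
#' transverse central difference of half-pixel pitch -- the row for detector
#' bin `s` is the difference of the interpolation rows at `s + ds/2` and
#' `s - ds/2`, scaled by `1/ds`. Applying `B` to a constant image therefore
#' yields (near-)zero for every ray fully inside the support.
#'
#' @param geometry a [scan_geometry()].
#' @param grid_size image size: a single side length or `c(rows, cols)`.
#' @return an object of class `differential_operator` holding the CSR triplet
#'   slots (`p`, `j`, `x`, zero-based), per-ray squared norms, the geometry
#'   and the grid size. Rays are ordered view-major: ray `(v - 1) * n_detector
#'   + d` is detector bin `d` of view `v`.
#' @examples
#' g <- scan_geometry(8, n_detector = 24)
#' op <- differential_operator(g, 16)
#' range(forward_project(op, matrix(1, 16, 16)))  # ~0 inside support
#' @export
differential_operator <- function(geometry, grid_size) {
  if (!inherits(geometry, "scan_geometry")) stop("geometry must be a scan_geometry")
  grid_size <- as.integer(if (length(grid_size) == 1L) c(grid_size, grid_size) else grid_size)
  if (length(grid_size) != 2L || any(grid_size < 1L)) stop("invalid grid_size")
  csr <- build_diff_operator_cpp(view_angles(geometry), geometry$n_detector,
                                 geometry$detector_spacing,
                                 grid_size[1], grid_size[2])
  structure(list(p = csr$p, j = csr$j, x = csr$x, row_norm2 = csr$row_norm2,
                 geometry = geometry, grid_size = grid_size),
            class = "differential_operator")
}

#' @export
print.differential_operator <- function(x, ...) {
  cat(sprintf("differential operator: %d rays (%d views x %d bins) -> %d x %d grid, %d nonzeros\n",
              x$geometry$n_views * x$geometry$n_detector, x$geometry$n_views,
              x$geometry$n_detector, x$grid_size[1], x$grid_size[2],
              length(x$x)))
  invisible(x)
}

#' Dense matrix form of a differential operator
#'
#' Intended for small grids (tests, inspection); the dense form of a
#' realistic operator is huge.
#'
#' @param x a [differential_operator()].
#' @param ... unused.
#' @export
as.matrix.differential_operator <- function(x, ...) {
  n_rays <- length(x$p) - 1L
  npix <- prod(x$grid_size)
  M <- matrix(0, n_rays, npix)
  for (i in seq_len(n_rays)) {
    rng <- (x$p[i] + 1L):(x$p[i + 1L])
    if (x$p[i + 1L] > x$p[i]) M[i, x$j[rng] + 1L] <- x$x[rng]
  }
  M
}

# image matrix -> vector in the operator's pixel ordering (row-major)
img_to_vec <- function(x, op) {
  if (!is.matrix(x) || !all(dim(x) == op$grid_size))
    stop("image shape does not match the operator grid")
  as.vector(t(x))
}

vec_to_img <- function(v, op) {
  matrix(v, op$grid_size[1], op$grid_size[2], byrow = TRUE)
}

#' Differential forward projection
#'
#' Computes the refraction-angle sinogram `y = B x`, linear in `x`.
#'
#' @param op a [differential_operator()].
#' @param x image matrix matching the operator grid.
#' @return sinogram matrix of shape `(n_views, n_detector)` with the scan
#'   geometry attached as attribute `"geometry"`.
#' @export
forward_project <- function(op, x) {
  y <- csr_matvec_cpp(op$p, op$j, op$x, img_to_vec(x, op))
  sino <- matrix(y, op$geometry$n_views, op$geometry$n_detector, byrow = TRUE)
  attr(sino, "geometry") <- op$geometry
  sino
}

sino_to_vec <- function(y, op) {
  if (!is.matrix(y) || nrow(y) != op$geometry$n_views ||
      ncol(y) != op$geometry$n_detector)
    stop("sinogram shape does not match the operator geometry")
  as.vector(t(y))
}
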