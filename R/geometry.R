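#' Parallel-beam scan geometry
#'
#' Describes a parallel-beam DPC-CT acquisition: the set of view angles and
#' the detector sampling. Angles start at 0 and advance by
#' `angular_interval_deg`; the product `n_views * angular_interval_deg` must
#' equal `angular_range_deg`.
#'
#' @param n_views number of projection angles (>= 1).
#' @param angular_range_deg total angular span in degrees (default 180).
#' @param angular_interval_deg spacing between views in degrees; defaults to
#'   `angular_range_deg / n_views`.
#' @param n_detector number of detector bins (>= 1).
#' @param detector_spacing detector bin width in image-pixel units.
#' @return an object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(180, n_detector = 363)
#' head(view_angles(g, "degrees"))
#' @export
scan_geometry <- function(n_views, angular_range_deg = 180,
                          angular_interval_deg = NULL,
                          n_detector, detector_spacing = 1) {
  if (is.null(angular_interval_deg))
    angular_interval_deg <- angular_range_deg / n_views
  n_views <- as.integer(n_views)
  n_detector <- as.integer(n_detector)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (n_detector < 1L) stop("n_detector must be >= 1")
  if (angular_interval_deg <= 0) stop("angular_interval_deg must be > 0")
  if (abs(n_views * angular_interval_deg - angular_range_deg) > 1e-9)
    stop("n_views * angular_interval_deg must equal angular_range_deg")
  structure(list(n_views = n_views,
                 angular_range_deg = angular_range_deg,
                 angular_interval_deg = angular_interval_deg,
                 n_detector = n_detector,
                 detector_spacing = detector_spacing,
                 beam_model = "parallel"),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("parallel-beam scan geometry: %d views / %g deg (interval %g deg), %d detector bins (spacing %g px)\n",
              x$n_views, x$angular_range_deg, x$angular_interval_deg,
              x$n_detector, x$detector_spacing))
  invisible(x)
}

#' View angles of a scan geometry
#'
#' Angles start at 0, are strictly increasing with spacing
#' `angular_interval_deg`, and all lie below `angular_range_deg`.
#'
#' @param geometry a [scan_geometry()].
#' @param unit `"radians"` (default) or `"degrees"`.
#' @return numeric vector of length `n_views`.
#' @export
view_angles <- function(geometry, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  deg <- (seq_len(geometry$n_views) - 1) * geometry$angular_interval_deg
  if (unit == "degrees") deg else deg * pi / 180
}

#' Angular downsampling of a scan geometry
#'
#' Keeps every `factor`-th view of the dense angle set, emulating a few-view
#' acquisition derived from a dense reference scan (e.g. factor 18 turns
#' 180 views / 1 degree into 10 views / 18 degrees).
#'
#' @param geometry dense [scan_geometry()].
#' @param factor integer downsampling factor; must divide `n_views`.
#' @return the downsampled `scan_geometry`.
#' @export
downsample_geometry <- function(geometry, factor) {
  factor <- as.integer(factor)
  if (factor < 1L || geometry$n_views %% factor != 0L)
    stop("factor must be a positive divisor of n_views")
  scan_geometry(n_views = geometry$n_views %/% factor,
                angular_range_deg = geometry$angular_range_deg,
                angular_interval_deg = geometry$angular_interval_deg * factor,
                n_detector = geometry$n_detector,
                detector_spacing = geometry$detector_spacing)
}

#' Default detector bin count for an n x n image
#'
#' `ceiling(n * sqrt(2))`, so the full image diagonal is covered at every
#' view angle.
#'
#' @param n image side length in pixels.
#' @return integer bin count.
#' @export
default_n_detector <- function(n) as.integer(ceiling(n * sqrt(2)))
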