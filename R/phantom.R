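#' Shepp-Logan ellipse tables
#'
#' The ten-ellipse head phantom, either with the modified (Toft) contrast --
#' whose composite values fall in \[0, 1\] and suit a \[0, 1\] display window --
#' or the classic low-contrast original. Columns: additive intensity `A`,
#' semi-axes `a`, `b`, centre `x0`, `y0` (in \[-1, 1\] phantom coordinates,
#' +y up), and rotation `phi_deg` (counter-clockwise).
#'
#' @param variant `"modified"` (default) or `"classic"`.
#' @return a data.frame with one row per ellipse.
#' @export
shepp_logan_ellipses <- function(variant = c("modified", "classic")) {
  variant <- match.arg(variant)
  A <- if (variant == "modified")
    c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  else
    c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  data.frame(
    A = A,
    a  = c(0.69, 0.6624, 0.1100, 0.1600, 0.2100, 0.0460, 0.0460, 0.0460, 0.0230, 0.0230),
    b  = c(0.92, 0.8740, 0.3100, 0.4100, 0.2500, 0.0460, 0.0460, 0.0230, 0.0230, 0.0460),
    x0 = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0 = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi_deg = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Shepp-Logan refraction-index-decrement phantom
#'
#' Samples the ellipse phantom on an `n x n` pixel grid. Values are the sum of
#' the intensities of all ellipses containing the pixel centre; outside the
#' outer ellipse the image is exactly zero. Deterministic.
#'
#' @param n grid side length (>= 16).
#' @param variant contrast variant passed to [shepp_logan_ellipses()]; ignored
#'   when `ellipses` is supplied.
#' @param ellipses optional custom ellipse table in the
#'   [shepp_logan_ellipses()] format.
#' @return an `n x n` numeric matrix (refraction index decrement, display
#'   units).
#' @examples
#' ph <- shepp_logan(64)
#' range(ph)
#' @export
shepp_logan <- function(n, variant = c("modified", "classic"), ellipses = NULL) {
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  if (is.null(ellipses)) ellipses <- shepp_logan_ellipses(match.arg(variant))
  c0 <- (n - 1) / 2
  x <- ((seq_len(n) - 1) - c0) / (n / 2)   # column -> x
  y <- -(((seq_len(n) - 1) - c0) / (n / 2)) # row -> y (+y up)
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(y, n, n)
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(ellipses))) {
    e <- ellipses[k, ]
    phi <- e$phi_deg * pi / 180
    dx <- X - e$x0; dy <- Y - e$y0
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    img <- img + e$A * ((u / e$a)^2 + (v / e$b)^2 <= 1)
  }
  # intensity sums like 1 - 0.8 - 0.2 should be exact zeros, not -5e-17
  img[abs(img) < 1e-12] <- 0
  img
}
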