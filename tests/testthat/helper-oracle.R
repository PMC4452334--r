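# Independent dense-sampling Radon oracle: integrates the bilinearly
# interpolated image along each ray with a fine step. Used to cross-check the
# Joseph-based differential projector.
radon_oracle <- function(img, theta, s_vec, tstep = 0.25) {
  n <- nrow(img); c0 <- (n - 1) / 2
  ct <- cos(theta); st <- sin(theta)
  tmax <- n / sqrt(2) + 2
  tt <- seq(-tmax, tmax, by = tstep)
  vapply(s_vec, function(s) {
    x <- s * ct - tt * st; y <- s * st + tt * ct
    rf <- c0 - y; cf <- x + c0
    i0 <- floor(rf); j0 <- floor(cf); fr <- rf - i0; fc <- cf - j0
    val <- 0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      w <- (if (di == 0) 1 - fr else fr) * (if (dj == 0) 1 - fc else fc)
      ok <- ii >= 0 & ii < n & jj >= 0 & jj < n
      v <- numeric(length(tt)); v[ok] <- img[cbind(ii[ok] + 1, jj[ok] + 1)]
      val <- val + sum(w * v)
    }
    val * tstep
  }, numeric(1))
}

# oracle differential sinogram: central difference of the oracle projections
# at the same half-pixel pitch the operator uses
oracle_diff_sino <- function(img, geometry) {
  nd <- geometry$n_detector
  ds <- geometry$detector_spacing
  s_vec <- ((0:(nd - 1)) - (nd - 1) / 2) * ds
  angs <- view_angles(geometry)
  t(vapply(angs, function(a) {
    (radon_oracle(img, a, s_vec + ds / 2) -
       radon_oracle(img, a, s_vec - ds / 2)) / ds
  }, numeric(nd)))
}

# smooth off-centre Gaussian blob test image
gaussian_blob <- function(n, cx = 5, cy = -3, width = 8) {
  c0 <- (n - 1) / 2
  xs <- (seq_len(n) - 1) - c0
  X <- matrix(xs, n, n, byrow = TRUE); Y <- -matrix(xs, n, n)
  exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
}

centered_disk <- function(n, radius = n / 4) {
  c0 <- (n - 1) / 2
  xs <- (seq_len(n) - 1) - c0
  X <- matrix(xs, n, n, byrow = TRUE); Y <- -matrix(xs, n, n)
  (X^2 + Y^2 <= radius^2) * 1.0
}
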