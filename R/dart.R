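#' Configuration for iterative DPC-CT reconstruction
#'
#' @param n_iterations number of full sweeps (>= 1).
#' @param relaxation ART relaxation factor beta in (0, 1].
#' @param regularizer `"none"` (plain DART), `"tv"` (total-variation step per
#'   sweep) or `"bm3d"` (BM3D collaborative filter per sweep plus
#'   frequency-domain excitation noise).
#' @param lambda_reg TV gradient-descent step size (used by `"tv"`).
#' @param tv_subiterations TV gradient sub-iterations per sweep.
#' @param excitation_sigma std of the frequency-domain excitation noise.
#'   `NULL` (default) uses a geometrically decaying schedule: the injected
#'   image-domain noise sd starts at `excitation_sd0` and shrinks by
#'   `excitation_decay` every sweep (a stirring-then-polishing anneal; a
#'   constant sigma accumulates a null-space random walk and prevents
#'   convergence). A single number fixes sigma for every sweep; a function
#'   `f(k, n_iterations, image, mask)` may implement any custom rule (e.g.
#'   [adaptive_excitation_sigma()] tied to the current spectrum).
#' @param excitation_sd0 image-domain noise sd injected at the first sweep
#'   (display units).
#' @param excitation_decay per-sweep geometric decay factor of the schedule.
#' @param bm3d_every apply the BM3D filter every this many sweeps.
#' @param bm3d_params a [bm3d_params()] object (defaults used when `NULL`).
#' @param measured_halfwidth_deg angular half-width (degrees) credited to each
#'   measured view when building the unmeasured-frequency mask; the default
#'   0.5 treats each view as covering the 1-degree wedge of a dense reference
#'   scan, so a 180-view / 1-degree scan has no unmeasured region.
#' @param log_every evaluate the residual norm (one extra forward projection)
#'   and the ground-truth MSE only every this many sweeps; other sweeps log
#'   `NA`. The final sweep is always evaluated.
#' @param seed RNG seed for the excitation noise (and random ray ordering).
#' @param initial_image starting image; `NULL` means all zeros.
#' @param nonneg clamp the image to delta >= 0 after each sweep.
#' @param random_order visit rays in a random order each sweep instead of the
#'   fixed view-major raster order.
#' @return an object of class `iterative_config`.
#' @export
iterative_config <- function(n_iterations = 100, relaxation = 0.5,
                             regularizer = c("none", "tv", "bm3d"),
                             lambda_reg = 1e-4, tv_subiterations = 20L,
                             excitation_sigma = NULL,
                             excitation_sd0 = 0.015, excitation_decay = 0.9973,
                             bm3d_every = 1L,
                             bm3d_params = NULL,
                             measured_halfwidth_deg = 0.5, log_every = 1L,
                             seed = 1L,
                             initial_image = NULL, nonneg = TRUE,
                             random_order = FALSE) {
  regularizer <- match.arg(regularizer)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (relaxation <= 0 || relaxation > 1) stop("relaxation must lie in (0, 1]")
  if (is.numeric(excitation_sigma) && excitation_sigma < 0)
    stop("excitation_sigma must be >= 0")
  bm3d_every <- as.integer(bm3d_every)
  if (bm3d_every < 1L) stop("bm3d_every must be >= 1")
  structure(list(n_iterations = n_iterations, relaxation = relaxation,
                 regularizer = regularizer, lambda_reg = lambda_reg,
                 tv_subiterations = as.integer(tv_subiterations),
                 excitation_sigma = excitation_sigma,
                 excitation_sd0 = excitation_sd0,
                 excitation_decay = excitation_decay,
                 bm3d_every = bm3d_every, bm3d_params = bm3d_params,
                 measured_halfwidth_deg = measured_halfwidth_deg,
                 log_every = as.integer(log_every),
                 seed = seed, initial_image = initial_image, nonneg = nonneg,
                 random_order = random_order),
            class = "iterative_config")
}

#' One DART sweep (relaxed Kaczmarz pass)
#'
#' One full pass of row-action ART over all rays: for ray `i`,
#' `x <- x + beta (y_i - <b_i, x>) / ||b_i||^2 b_i`, skipping rays with zero
#' norm, optionally clamping to nonnegative values at the end of the sweep.
#'
#' @param x current image matrix.
#' @param y sinogram matrix matching the operator geometry.
#' @param op a [differential_operator()].
#' @param relaxation beta in (0, 1].
#' @param nonneg clamp to `x >= 0` after the sweep.
#' @param order optional 1-based ray visiting order (default: view-major
#'   raster order).
#' @return the updated image matrix.
#' @export
dart_sweep <- function(x, y, op, relaxation = 0.5, nonneg = TRUE, order = NULL) {
  if (all(op$row_norm2 == 0)) stop("degenerate system: all operator rows are zero")
  n_rays <- length(op$row_norm2)
  ord <- if (is.null(order)) seq_len(n_rays) else as.integer(order)
  xv <- kaczmarz_sweep_cpp(op$p, op$j, op$x, op$row_norm2, sino_to_vec(y, op),
                           img_to_vec(x, op), relaxation, 1L, nonneg, ord - 1L)
  vec_to_img(xv, op)
}

#' Total-variation regularization step
#'
#' `n_subiterations` gradient-descent steps on smoothed isotropic total
#' variation with step size `lambda_reg`. A zero step returns the input
#' bit-exactly.
#'
#' @param x image matrix.
#' @param lambda_reg step size (>= 0).
#' @param n_subiterations number of descent steps.
#' @return regularized image matrix.
#' @export
tv_regularize <- function(x, lambda_reg, n_subiterations = 20L) {
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (lambda_reg == 0) return(x)
  tv_descent_cpp(x, lambda_reg, as.integer(n_subiterations), 1e-8)
}

#' Unmeasured-frequency mask of a few-view scan
#'
#' By the central-slice theorem each view contributes the spectrum line along
#' its detector-axis direction; a frequency sample is *measured* when its
#' polar angle lies within `measured_halfwidth_deg` of some view angle
#' (modulo 180 degrees), and unmeasured otherwise. The DC sample is always
#' treated as measured.
#'
#' @param geometry a [scan_geometry()].
#' @param grid_size image size (side length or `c(rows, cols)`).
#' @param measured_halfwidth_deg angular half-width credited to each view.
#' @return logical matrix in FFT index order, `TRUE` = unmeasured.
#' @export
frequency_mask <- function(geometry, grid_size, measured_halfwidth_deg = 0.5) {
  grid_size <- as.integer(if (length(grid_size) == 1L) c(grid_size, grid_size) else grid_size)
  nr <- grid_size[1]; nc <- grid_size[2]
  ki <- 0:(nr - 1); ki <- ifelse(ki > nr / 2, ki - nr, ki)
  kj <- 0:(nc - 1); kj <- ifelse(kj > nc / 2, kj - nc, kj)
  FY <- -matrix(ki, nr, nc)        # row frequency -> y (up) component
  FX <- matrix(kj, nr, nc, byrow = TRUE)
  alpha <- atan2(FY, FX) %% pi
  hw <- measured_halfwidth_deg * pi / 180
  measured <- matrix(FALSE, nr, nc)
  for (th in view_angles(geometry)) {
    d <- abs(((alpha - th + pi / 2) %% pi) - pi / 2)
    measured <- measured | d <= hw
  }
  measured[1, 1] <- TRUE           # DC
  !measured
}

#' Excitation noise in the unmeasured frequency region
#'
#' Adds seeded Hermitian-symmetric complex Gaussian noise (per-coefficient
#' complex variance `sigma^2`) to the 2-D FFT of the image, but only on
#' frequency samples in the unmeasured angular region of the scan (see
#' [frequency_mask()]); measured-region coefficients are left untouched and
#' the output is real. This stimulates recovery of the missing spectral
#' components during iterative few-view reconstruction.
#'
#' @param x image matrix.
#' @param geometry the (few-view) [scan_geometry()].
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional seed; `NULL` draws from (and advances) the current
#'   RNG stream.
#' @param measured_halfwidth_deg see [frequency_mask()].
#' @param mask optional precomputed unmeasured mask (saves recomputation in
#'   loops).
#' @return perturbed image matrix (real).
#' @export
excitation_noise <- function(x, geometry, sigma, seed = NULL,
                             measured_halfwidth_deg = 0.5, mask = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  nr <- nrow(x); nc <- ncol(x)
  Fq <- stats::fft(x)
  if (sigma > 0) {
    if (is.null(mask))
      mask <- frequency_mask(geometry, c(nr, nc), measured_halfwidth_deg)
    if (any(mask)) {
      if (!is.null(seed)) {
        old <- get0(".Random.seed", envir = globalenv())
        set.seed(seed)
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      }
      Z <- matrix(complex(real = rnorm(nr * nc, 0, sigma / sqrt(2)),
                          imaginary = rnorm(nr * nc, 0, sigma / sqrt(2))),
                  nr, nc)
      # Hermitian-symmetrize so the inverse transform stays real; the sqrt(2)
      # restores per-coefficient variance sigma^2 after pair averaging
      conj_i <- c(1L, rev(seq_len(nr - 1L) + 1L))
      conj_j <- c(1L, rev(seq_len(nc - 1L) + 1L))
      Zh <- sqrt(2) * (Z + Conj(Z[conj_i, conj_j])) / 2
      Fq[mask] <- Fq[mask] + Zh[mask]
    }
  }
  Re(stats::fft(Fq, inverse = TRUE)) / (nr * nc)
}

#' Spectrum-adaptive excitation sigma
#'
#' Half the standard deviation of the current image's FFT magnitudes over the
#' unmeasured region. Usable as a custom `excitation_sigma` rule in
#' [iterative_config()]; note that, unlike the default decaying schedule, it
#' does not vanish as the reconstruction converges, so it leaves a noise
#' floor.
#'
#' @param k,n_iterations current and total sweep count (unused).
#' @param image current image matrix.
#' @param mask unmeasured-frequency mask from [frequency_mask()].
#' @return noise std (frequency-domain units).
#' @export
adaptive_excitation_sigma <- function(k, n_iterations, image, mask) {
  if (!any(mask)) return(0)
  0.5 * stats::sd(Mod(stats::fft(image)[mask]))
}

# geometric image-domain anneal mapped to frequency-domain units
schedule_excitation_sigma <- function(k, sd0, decay, npix, n_masked) {
  if (n_masked == 0) return(0)
  sd0 * decay^(k - 1) * npix / sqrt(n_masked)
}

#' Iterative DPC-CT reconstruction (DART / DART_TV / DART_BM3D)
#'
#' Runs the regularized DART loop: each sweep is one relaxed Kaczmarz pass
#' over all rays, followed (depending on `config$regularizer`) by a TV
#' descent step, or by the BM3D collaborative filter plus excitation noise in
#' the unmeasured frequency region (the explicit-filtering scheme; the noise
#' injection is skipped after the final sweep since it only seeds the next
#' one). Fully reproducible for a given config and seed.
#'
#' @param y sinogram matrix.
#' @param op a [differential_operator()].
#' @param config an [iterative_config()].
#' @param ground_truth optional reference image; when given, per-sweep MSE is
#'   logged.
#' @return list of class `dpc_reconstruction` with elements `image`, `log`
#'   (data.frame: sweep, residual, mse, wall) and `config`. The residual
#'   `||y - B x_k||` is evaluated after the sweep's ART and filtering steps,
#'   before any excitation noise.
#' @export
reconstruct <- function(y, op, config, ground_truth = NULL) {
  if (!inherits(config, "iterative_config")) stop("config must be an iterative_config")
  geom <- op$geometry
  x <- config$initial_image
  if (is.null(x)) x <- matrix(0, op$grid_size[1], op$grid_size[2])
  if (!is.null(config$seed)) set.seed(config$seed)
  yv <- sino_to_vec(y, op)
  use_bm3d <- config$regularizer == "bm3d"
  mask <- if (use_bm3d)
    frequency_mask(geom, op$grid_size, config$measured_halfwidth_deg)
  else NULL
  bp <- config$bm3d_params
  if (use_bm3d && is.null(bp)) bp <- bm3d_params()
  n_rays <- length(op$row_norm2)

  residual <- mse_log <- wall <- numeric(config$n_iterations)
  for (k in seq_len(config$n_iterations)) {
    ord <- if (config$random_order) sample.int(n_rays) else NULL
    x <- dart_sweep(x, y, op, config$relaxation, config$nonneg, ord)
    if (config$regularizer == "tv") {
      x <- tv_regularize(x, config$lambda_reg, config$tv_subiterations)
    } else if (use_bm3d && k %% config$bm3d_every == 0L) {
      x <- bm3d_denoise(x, bp)
    }
    if (!all(is.finite(x))) stop(sprintf("non-finite image at sweep %d", k))
    if (k %% config$log_every == 0L || k == config$n_iterations) {
      residual[k] <- sqrt(sum((yv - csr_matvec_cpp(op$p, op$j, op$x, img_to_vec(x, op)))^2))
      mse_log[k] <- if (is.null(ground_truth)) NA_real_ else mse(x, ground_truth)
    } else {
      residual[k] <- NA_real_
      mse_log[k] <- NA_real_
    }
    wall[k] <- as.numeric(Sys.time())
    if (use_bm3d && k < config$n_iterations) {
      es <- config$excitation_sigma
      sig <- if (is.null(es))
        schedule_excitation_sigma(k, config$excitation_sd0,
                                  config$excitation_decay, prod(op$grid_size),
                                  sum(mask))
      else if (is.function(es)) es(k, config$n_iterations, x, mask)
      else es
      x <- excitation_noise(x, geom, sig, seed = NULL,
                            measured_halfwidth_deg = config$measured_halfwidth_deg,
                            mask = mask)
    }
  }
  structure(list(image = x,
                 log = data.frame(sweep = seq_len(config$n_iterations),
                                  residual = residual, mse = mse_log,
                                  wall = wall),
                 config = config),
            class = "dpc_reconstruction")
}

#' @export
print.dpc_reconstruction <- function(x, ...) {
  cat(sprintf("DPC reconstruction: %d x %d image, %d sweeps (%s), final residual %.4g\n",
              nrow(x$image), ncol(x$image), nrow(x$log),
              x$config$regularizer, x$log$residual[nrow(x$log)]))
  invisible(x)
}
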