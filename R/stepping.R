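# Talbot-Lau phase stepping: per-pixel intensity oscillation over grating
# steps, I(x_g) = a0 (1 + V cos(2 pi x_g / p2 + phi1)), and the retrieval of
# attenuation (T), dark-field (S) and differential-phase (DP) images from a
# sample/reference stack pair.

#' Wrap phase values into (-pi, pi]
#'
#' @param x numeric (radians).
#' @return wrapped values.
#' @export
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Simulate a phase-stepping acquisition
#'
#' Generates per-pixel intensity oscillation stacks for a reference scan
#' (mean `a0_ref`, visibility `v_ref`, phase 0) and a sample scan whose mean
#' is attenuated by `exp(-T)`, visibility by `exp(-S)`, and phase shifted by
#' `DP`. Grating steps cover exactly one analyzer period `p2` uniformly, so
#' the first-harmonic retrieval is exact in the noiseless case. Optional
#' Poisson counting noise treats intensities as expected photon counts.
#'
#' @param T attenuation image (-log amplitude ratio), matrix.
#' @param DP differential-phase image in radians, same shape.
#' @param S dark-field image (-log visibility ratio), same shape.
#' @param n_steps number of grating steps (>= 3).
#' @param a0_ref reference mean intensity (> 0), e.g. photon counts.
#' @param v_ref reference visibility in \[0, 1\].
#' @param p2 analyzer-grating period (arbitrary units; step positions are in
#'   these units).
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed used when `noise = "poisson"`.
#' @return list with 3-D arrays `sample` and `reference` of shape
#'   `(n_steps, rows, cols)`, plus `step_positions`, `p2`, `a0_ref`, `v_ref`.
#' @export
simulate_phase_stepping <- function(T, DP, S, n_steps = 8, a0_ref = 100,
                                    v_ref = 0.5, p2 = 1,
                                    noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  n_steps <- as.integer(n_steps)
  if (n_steps < 3L) stop("n_steps must be >= 3 (three unknowns a0, a1, phi1)")
  if (a0_ref <= 0) stop("a0_ref must be positive")
  if (v_ref < 0 || v_ref > 1) stop("v_ref must lie in [0, 1]")
  if (!all(dim(T) == dim(DP)) || !all(dim(T) == dim(S)))
    stop("T, DP, S must have the same shape")
  d <- dim(T)
  xg <- (seq_len(n_steps) - 1) / n_steps * p2
  phase <- 2 * pi * xg / p2
  a0_s <- a0_ref * exp(-T)
  v_s <- v_ref * exp(-S)
  ref <- array(0, c(n_steps, d))
  smp <- array(0, c(n_steps, d))
  for (k in seq_len(n_steps)) {
    ref[k, , ] <- a0_ref * (1 + v_ref * cos(phase[k]))
    smp[k, , ] <- a0_s * (1 + v_s * cos(phase[k] + DP))
  }
  if (noise == "poisson") {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    ref[] <- rpois(length(ref), ref)
    smp[] <- rpois(length(smp), smp)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  list(sample = smp, reference = ref, step_positions = xg, p2 = p2,
       a0_ref = a0_ref, v_ref = v_ref)
}

# zeroth and first discrete Fourier components of a stepping stack
# stack: (n_steps, rows, cols); returns list(a0, a1, phi1) as matrices
stepping_fit <- function(stack) {
  d <- dim(stack)
  n <- d[1]
  M <- matrix(stack, n, d[2] * d[3])
  a0 <- colMeans(M)
  w <- exp(-2i * pi * (seq_len(n) - 1) / n)
  c1 <- as.vector(crossprod(w, M))  # sum_k I_k e^{-2 pi i k / n}
  a1 <- 2 * Mod(c1) / n
  phi1 <- Arg(c1)
  list(a0 = matrix(a0, d[2], d[3]), a1 = matrix(a1, d[2], d[3]),
       phi1 = matrix(phi1, d[2], d[3]))
}

#' Retrieve attenuation, dark-field and differential-phase images
#'
#' Extracts per-pixel `(a0, a1, phi1)` as the zeroth and first discrete
#' Fourier components of each stepping series, then forms
#' `T = -log(a0_s / a0_r)`, `S = -log(V_s / V_r)` with `V = a1 / a0`, and
#' `DP = phi1_s - phi1_r` wrapped into `(-pi, pi]`. Pixels with nonpositive
#' mean intensity in either stack are set to `NaN` with a warning.
#'
#' @param sample,reference 3-D stacks `(n_steps, rows, cols)` as produced by
#'   [simulate_phase_stepping()], with >= 3 steps uniformly covering one
#'   period.
#' @return list of matrices `T`, `S`, `DP` and the per-stack fits
#'   `fit_sample`, `fit_reference` (each with `a0`, `a1`, `phi1`).
#' @export
retrieve_information <- function(sample, reference) {
  if (length(dim(sample)) != 3L || !all(dim(sample) == dim(reference)))
    stop("sample and reference stacks must be 3-D arrays of equal shape")
  if (dim(sample)[1] < 3L) stop("need at least 3 grating steps")
  fs <- stepping_fit(sample)
  fr <- stepping_fit(reference)
  bad <- fs$a0 <= 0 | fr$a0 <= 0
  if (any(bad)) {
    warning(sprintf("%d pixel(s) with nonpositive mean intensity flagged as NaN", sum(bad)))
    fs$a0[bad] <- NaN
    fr$a0[bad] <- NaN
  }
  Tm <- -log(fs$a0 / fr$a0)
  S <- -log((fs$a1 / fs$a0) / (fr$a1 / fr$a0))
  DP <- wrap_phase(fs$phi1 - fr$phi1)
  DP[bad] <- NaN
  S[bad] <- NaN
  list(T = Tm, S = S, DP = DP, fit_sample = fs, fit_reference = fr)
}
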