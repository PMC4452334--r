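#' BM3D filter parameters
#'
#' Parameters of the single-stage (hard-threshold) BM3D collaborative filter.
#' Block distance is the per-pixel mean squared difference
#' `||Z1 - Z2||^2 / N_mat^2`, so `match_threshold` lives on the squared
#' intensity scale; the default 0.05 corresponds to the canonical matching
#' threshold for images on a \[0, 1\] scale.
#'
#' @param block_size block side length `N_mat` (>= 2).
#' @param step block-grid stride (>= 1; a final block clamped to the image
#'   border guarantees full coverage). Smaller strides give denser matching
#'   and noticeably better filtering at roughly quadratic cost; 3 balances
#'   the two.
#' @param search_window half-width (pixels) of the square matching
#'   neighborhood around the reference block.
#' @param match_threshold maximum block distance for inclusion in a group.
#' @param max_group maximum blocks per group (>= 1).
#' @param hard_threshold coefficient cutoff as a multiple of `sigma_denoise`.
#' @param sigma_denoise assumed noise std; `NULL` (default) estimates it per
#'   call from the finest diagonal Haar subband
#'   (`median(|d|) / 0.6745`, the robust MAD estimator).
#' @param literal_eq11 use the unweighted indicator denominator in the
#'   aggregation instead of the similarity-weighted average (for comparison
#'   only).
#' @return an object of class `bm3d_params`.
#' @export
bm3d_params <- function(block_size = 8L, step = 3L, search_window = 16L,
                        match_threshold = 0.05, max_group = 16L,
                        hard_threshold = 2.7, sigma_denoise = NULL,
                        literal_eq11 = FALSE) {
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("block_size must be >= 2")
  if (as.integer(step) < 1L) stop("step must be >= 1")
  if (as.integer(max_group) < 1L) stop("max_group must be >= 1")
  if (match_threshold < 0 || hard_threshold < 0) stop("thresholds must be >= 0")
  if (!is.null(sigma_denoise) && sigma_denoise < 0) stop("sigma_denoise must be >= 0")
  structure(list(block_size = block_size, step = as.integer(step),
                 search_window = as.integer(search_window),
                 match_threshold = match_threshold,
                 max_group = as.integer(max_group),
                 hard_threshold = hard_threshold,
                 sigma_denoise = sigma_denoise,
                 literal_eq11 = isTRUE(literal_eq11)),
            class = "bm3d_params")
}

#' Robust noise-level estimate
#'
#' `median(|d|) / 0.6745` over the finest diagonal Haar subband of the image
#' (disjoint 2x2 cells).
#'
#' @param image numeric matrix.
#' @return estimated noise standard deviation.
#' @export
estimate_noise_sd <- function(image) {
  nr <- 2L * (nrow(image) %/% 2L); nc <- 2L * (ncol(image) %/% 2L)
  a <- image[seq(1L, nr, 2L), seq(1L, nc, 2L)]
  b <- image[seq(1L, nr, 2L), seq(2L, nc, 2L)]
  cc <- image[seq(2L, nr, 2L), seq(1L, nc, 2L)]
  d <- image[seq(2L, nr, 2L), seq(2L, nc, 2L)]
  diag_band <- (a - b - cc + d) / 2
  stats::median(abs(diag_band)) / 0.6745
}

#' Block distance
#'
#' Squared Euclidean distance between two equally sized blocks divided by
#' `N_mat^2` (i.e. the per-pixel mean squared difference). Symmetric, zero
#' iff the blocks are identical.
#'
#' @param z1,z2 square numeric matrices of equal side length.
#' @return nonnegative scalar.
#' @export
block_distance <- function(z1, z2) {
  if (!all(dim(z1) == dim(z2))) stop("blocks must have equal shape")
  sum((z1 - z2)^2) / length(z1)
}

# stride grid covering [1, n - N + 1], final position clamped to the border
bm3d_grid <- function(n, N, step) {
  g <- seq(1L, n - N + 1L, by = step)
  if (g[length(g)] != n - N + 1L) g <- c(g, n - N + 1L)
  g
}

#' Match similar blocks around a reference position
#'
#' Scans the block grid inside the search window, keeps candidates whose
#' [block_distance()] to the reference block is at most `match_threshold`,
#' sorts them by ascending distance (scan order breaks ties) and truncates to
#' `max_group`. The reference block is always the first member.
#'
#' @param image numeric matrix.
#' @param reference_position `c(row, col)` of the reference block's top-left
#'   pixel (1-based); must lie on or off the grid but fully inside the image.
#' @param params a [bm3d_params()].
#' @return an object of class `block_group`: `reference_position`,
#'   `member_positions` (matrix, one row per member), `distances`,
#'   `stacked_values` (array `block_size x block_size x n_members`).
#' @export
match_blocks <- function(image, reference_position, params = bm3d_params()) {
  N <- params$block_size
  rp <- as.integer(reference_position)
  if (length(rp) != 2L || any(rp < 1L) || rp[1] + N - 1L > nrow(image) ||
      rp[2] + N - 1L > ncol(image))
    stop("reference block must lie fully inside the image")
  ref <- image[rp[1]:(rp[1] + N - 1L), rp[2]:(rp[2] + N - 1L)]
  gr <- bm3d_grid(nrow(image), N, params$step)
  gc <- bm3d_grid(ncol(image), N, params$step)
  gr <- gr[abs(gr - rp[1]) <= params$search_window]
  gc <- gc[abs(gc - rp[2]) <= params$search_window]
  # the reference is always a member, whether or not it sits on the grid
  pos <- list(rp); dist <- -1
  for (r in gr) for (cl in gc) {   # row-major scan order
    if (r == rp[1] && cl == rp[2]) next
    blk <- image[r:(r + N - 1L), cl:(cl + N - 1L)]
    d <- block_distance(ref, blk)
    if (d <= params$match_threshold) {
      pos[[length(pos) + 1L]] <- c(r, cl)
      dist <- c(dist, d)
    }
  }
  ord <- order(dist)               # stable; reference (-1) first
  pos <- pos[ord]; dist <- pmax(dist[ord], 0)
  keep <- seq_len(min(length(pos), params$max_group))
  pos <- pos[keep]; dist <- dist[keep]
  stacked <- array(0, c(N, N, length(pos)))
  for (k in seq_along(pos))
    stacked[, , k] <- image[pos[[k]][1]:(pos[[k]][1] + N - 1L),
                            pos[[k]][2]:(pos[[k]][2] + N - 1L)]
  structure(list(reference_position = rp,
                 member_positions = do.call(rbind, pos),
                 distances = dist, stacked_values = stacked,
                 weight = NULL, n_nonzero = NULL),
            class = "block_group")
}

# orthonormal DCT-II matrix
dct_matrix <- function(N) {
  k <- 0:(N - 1)
  D <- sqrt(2 / N) * cos(pi * outer(k, 2 * k + 1) / (2 * N))
  D[1, ] <- sqrt(1 / N)
  D
}

# ordered orthonormal Haar transform of a vector of power-of-two length
haar_transform <- function(v, inverse = FALSE) {
  P <- length(v)
  if (P == 1L) return(v)
  s2 <- sqrt(0.5)
  if (!inverse) {
    len <- P
    while (len > 1L) {
      h <- len %/% 2L
      a <- v[seq(1L, len, 2L)]; b <- v[seq(2L, len, 2L)]
      v[1:h] <- (a + b) * s2
      v[(h + 1L):len] <- (a - b) * s2
      len <- h
    }
  } else {
    len <- 2L
    while (len <= P) {
      h <- len %/% 2L
      a <- v[1:h]; b <- v[(h + 1L):len]
      w <- numeric(len)
      w[seq(1L, len, 2L)] <- (a + b) * s2
      w[seq(2L, len, 2L)] <- (a - b) * s2
      v[1:len] <- w
      len <- len * 2L
    }
  }
  v
}

#' Collaborative hard-threshold filtering of a block group
#'
#' Applies the separable orthonormal 3-D transform (2-D DCT per block, 1-D
#' Haar along the stack, the stack padded to a power of two by repeating the
#' last block), zeroes coefficients smaller in magnitude than
#' `hard_threshold * sigma_denoise` (the group's global DC coefficient is
#' exempt so constants survive), inverse-transforms, and records the number
#' of surviving coefficients `N_har` and the group weight
#' `w = 1 / (sigma^2 N_har)` (`w = 1` when `N_har = 0` or `sigma = 0`).
#'
#' @param group a [match_blocks()] result.
#' @param params a [bm3d_params()]; `sigma_denoise` must be set (it is filled
#'   in by [bm3d_denoise()]).
#' @return the group with filtered `stacked_values`, `weight`, `n_nonzero`.
#' @export
collaborative_filter <- function(group, params = bm3d_params()) {
  st <- group$stacked_values
  N <- dim(st)[1]; s <- dim(st)[3]
  sigma <- params$sigma_denoise
  if (is.null(sigma)) sigma <- 0
  thr <- params$hard_threshold * sigma
  P <- 2^ceiling(log2(s))
  D <- dct_matrix(N)
  coefs <- array(0, c(N, N, P))
  for (k in seq_len(P))
    coefs[, , k] <- D %*% st[, , min(k, s)] %*% t(D)
  nhar <- 0L
  for (q in seq_len(N * N)) {
    a <- (q - 1) %% N + 1; b <- (q - 1) %/% N + 1
    col <- haar_transform(coefs[a, b, ])
    dc <- (a == 1L && b == 1L)
    zap <- abs(col) < thr
    if (dc) zap[1] <- FALSE
    col[zap] <- 0
    nhar <- nhar + sum(col != 0)
    coefs[a, b, ] <- haar_transform(col, inverse = TRUE)
  }
  out <- array(0, c(N, N, s))
  for (k in seq_len(s))
    out[, , k] <- t(D) %*% coefs[, , k] %*% D
  group$stacked_values <- out
  group$n_nonzero <- nhar
  group$weight <- if (sigma > 0 && nhar > 0) 1 / (sigma^2 * nhar) else 1
  group
}

#' Similarity-weighted aggregation of filtered block groups
#'
#' Every pixel becomes `sum(w * filtered value) / sum(w)` over all member
#' blocks covering it (with `literal_eq11 = TRUE`, the denominator counts the
#' 0/1 nonzero indicator instead of the weights). Every pixel must be covered
#' by at least one block.
#'
#' @param groups list of filtered [collaborative_filter()] groups.
#' @param image_shape `c(rows, cols)` of the output.
#' @param literal_eq11 see [bm3d_params()].
#' @return aggregated image matrix.
#' @export
aggregate_blocks <- function(groups, image_shape, literal_eq11 = FALSE) {
  num <- matrix(0, image_shape[1], image_shape[2])
  den <- matrix(0, image_shape[1], image_shape[2])
  covered <- matrix(FALSE, image_shape[1], image_shape[2])
  for (g in groups) {
    N <- dim(g$stacked_values)[1]
    for (k in seq_len(dim(g$stacked_values)[3])) {
      r <- g$member_positions[k, 1]; cl <- g$member_positions[k, 2]
      rows <- r:(r + N - 1L); cols <- cl:(cl + N - 1L)
      vals <- g$stacked_values[, , k]
      num[rows, cols] <- num[rows, cols] + g$weight * vals
      den[rows, cols] <- den[rows, cols] +
        if (literal_eq11) (vals != 0) else g$weight
      covered[rows, cols] <- TRUE
    }
  }
  if (!all(covered)) stop("internal error: uncovered pixel during aggregation")
  out <- num / den
  out[den == 0] <- 0
  out
}

#' BM3D denoising
#'
#' Full single-stage BM3D: block matching on the stride grid (one group per
#' grid reference block), collaborative hard-threshold filtering, and
#' similarity-weighted aggregation. Deterministic. The heavy lifting runs in
#' compiled code; [match_blocks()], [collaborative_filter()] and
#' [aggregate_blocks()] expose the identical pipeline stages for inspection.
#'
#' @param image numeric matrix (finite).
#' @param params a [bm3d_params()].
#' @return the filtered image matrix.
#' @examples
#' img <- matrix(0.5, 32, 32)
#' max(abs(bm3d_denoise(img, bm3d_params(sigma_denoise = 0.1)) - img))
#' @export
bm3d_denoise <- function(image, params = bm3d_params()) {
  if (!all(is.finite(image))) stop("image must be finite")
  sigma <- params$sigma_denoise
  if (is.null(sigma)) sigma <- estimate_noise_sd(image)
  bm3d_core_cpp(image, params$block_size, params$step, params$search_window,
                params$match_threshold, params$max_group,
                params$hard_threshold, sigma, !params$literal_eq11)
}
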