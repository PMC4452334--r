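test_that("constant images project to zero along full-chord rays", {
  n <- 32
  g <- scan_geometry(8, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  cval <- 3
  y <- forward_project(op, matrix(cval, n, n))
  s_vec <- ((0:(g$n_detector - 1)) - (g$n_detector - 1) / 2)
  angs <- view_angles(g)
  h <- n / 2
  # a ray is "fully inside the support" when it (and its half-pixel
  # neighbours) traverse the full constant chord without clipping the side
  # edges, i.e. where the square's projection profile is flat
  full_chord <- function(theta, s) {
    d <- c(-sin(theta), cos(theta)); u <- c(cos(theta), sin(theta))
    drive <- which.max(abs(d)); other <- 3L - drive
    tends <- (c(-h, h) - s * u[drive]) / d[drive]
    ends <- s * u[other] + tends * d[other]
    all(abs(ends) <= h - 1.5)
  }
  checked <- 0L
  for (v in seq_along(angs)) for (b in seq_along(s_vec)) {
    if (full_chord(angs[v], s_vec[b] - 1) && full_chord(angs[v], s_vec[b] + 1)) {
      expect_lt(abs(y[v, b]), 1e-6 * cval)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)  # the flat region is non-trivial for these angles
})

test_that("forward projection is linear and zero on the zero image", {
  n <- 24
  g <- scan_geometry(6, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  expect_true(all(forward_project(op, matrix(0, n, n)) == 0))
  set.seed(11)
  x1 <- matrix(runif(n * n), n, n)
  x2 <- matrix(runif(n * n), n, n)
  y12 <- forward_project(op, x1 + x2)
  expect_equal(y12, forward_project(op, x1) + forward_project(op, x2),
               tolerance = 1e-10)
})

test_that("rays missing the image support have all-zero coefficient rows", {
  n <- 16
  g <- scan_geometry(4, n_detector = 4 * n, detector_spacing = 1)
  op <- differential_operator(g, n)
  # outermost detector bins are far outside the n/sqrt(2) support radius
  nnz_per_row <- diff(op$p)
  edge_rows <- c(1:4, (4 * n - 3):(4 * n))   # first view's extreme bins
  expect_true(all(nnz_per_row[edge_rows] == 0))
  expect_true(any(nnz_per_row > 0))
})

test_that("operator matches the Radon-derivative oracle on smooth images", {
  n <- 64
  img <- gaussian_blob(n)
  g <- scan_geometry(8, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  y <- forward_project(op, img)
  y_oracle <- oracle_diff_sino(img, g)
  peak <- max(abs(y_oracle))
  expect_lt(max(abs(y - y_oracle)), 0.02 * peak)
})

test_that("centered-disk projection agrees with the oracle at the 0-degree view", {
  n <- 64
  img <- centered_disk(n, 16)
  g <- scan_geometry(4, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  y <- forward_project(op, img)
  yo <- oracle_diff_sino(img, g)
  expect_lt(max(abs(y[1, ] - yo[1, ])), 0.02 * max(abs(yo[1, ])))
})

test_that("per-view detector sums of differential projections telescope to zero", {
  n <- 64
  ph <- shepp_logan(n)
  g <- scan_geometry(12, n_detector = default_n_detector(n))
  y <- forward_project(differential_operator(g, n), ph)
  expect_lt(max(abs(rowSums(y))), 1e-3 * max(abs(y)) * ncol(y))
})

test_that("operator construction and projection reject mismatched shapes", {
  g <- scan_geometry(4, n_detector = 24)
  op <- differential_operator(g, 16)
  expect_error(forward_project(op, matrix(0, 17, 16)), "shape")
  expect_error(differential_operator(list(), 16), "scan_geometry")
  M <- as.matrix(op)
  expect_equal(dim(M), c(4L * 24L, 256L))
  set.seed(2)
  x <- matrix(rnorm(256), 16, 16)
  expect_equal(as.vector(M %*% as.vector(t(x))),
               as.vector(t(forward_project(op, x))), tolerance = 1e-12)
})
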