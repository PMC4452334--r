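test_that("a single consistent ray is solved exactly by one unit-relaxation update", {
  n <- 8
  g <- scan_geometry(1, n_detector = 1)
  op <- differential_operator(g, n)
  expect_gt(sum(op$row_norm2), 0)
  set.seed(3)
  x_true <- matrix(runif(n * n), n, n)
  y <- forward_project(op, x_true)
  x1 <- dart_sweep(matrix(0, n, n), y, op, relaxation = 1, nonneg = FALSE)
  expect_lt(abs(forward_project(op, x1)[1, 1] - y[1, 1]), 1e-12)
})

test_that("DART drives the residual down on a consistent dense system", {
  n <- 64
  ph <- shepp_logan(n)
  g <- scan_geometry(180, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  y <- forward_project(op, ph)
  r <- reconstruct(y, op, iterative_config(500, regularizer = "none"),
                   ground_truth = ph)
  expect_lt(r$log$residual[500], 0.01 * r$log$residual[1])
  expect_lt(r$log$mse[500], r$log$mse[1])
  expect_lt(r$log$residual[100], r$log$residual[1])
  expect_lt(r$log$residual[500], r$log$residual[100])
})

test_that("reconstruct with no regularizer reproduces iterated dart_sweep bit-exactly", {
  n <- 24
  ph <- gaussian_blob(n, width = 5)
  g <- scan_geometry(10, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  y <- forward_project(op, ph)
  r <- reconstruct(y, op, iterative_config(7, regularizer = "none"))
  x <- matrix(0, n, n)
  for (k in 1:7) x <- dart_sweep(x, y, op, 0.5)
  expect_identical(r$image, x)
})

test_that("degenerate all-zero systems are rejected", {
  g <- scan_geometry(2, n_detector = 4)
  op <- differential_operator(g, 8)
  op$x[] <- 0
  op$row_norm2[] <- 0
  expect_error(dart_sweep(matrix(0, 8, 8), matrix(0, 2, 4), op), "degenerate")
})

test_that("TV regularization is a no-op at zero strength and on constants", {
  x <- matrix(rnorm(400), 20, 20)
  expect_identical(tv_regularize(x, 0), x)
  cst <- matrix(2.5, 16, 16)
  expect_equal(tv_regularize(cst, 0.01, 10), cst, tolerance = 1e-14)
  expect_error(tv_regularize(x, -1), "lambda_reg")
})

test_that("TV regularization denoises a piecewise-constant phantom", {
  set.seed(8)
  n <- 64
  ph <- shepp_logan(n)
  noisy <- ph + matrix(rnorm(n * n, 0, 0.05), n, n)
  sm <- tv_regularize(noisy, 0.002, 10)
  expect_lt(mse(sm, ph), mse(noisy, ph))
})

test_that("iterative_config rejects invalid settings", {
  expect_error(iterative_config(0), "n_iterations")
  expect_error(iterative_config(10, relaxation = 0), "relaxation")
  expect_error(iterative_config(10, relaxation = 1.5), "relaxation")
  expect_error(iterative_config(10, excitation_sigma = -1), "excitation_sigma")
  expect_error(iterative_config(10, bm3d_every = 0), "bm3d_every")
})

test_that("random ray ordering stays reproducible under the config seed", {
  n <- 24
  ph <- gaussian_blob(n, width = 5)
  g <- scan_geometry(10, n_detector = default_n_detector(n))
  op <- differential_operator(g, n)
  y <- forward_project(op, ph)
  cfg <- iterative_config(5, regularizer = "none", random_order = TRUE, seed = 4)
  r1 <- reconstruct(y, op, cfg)
  r2 <- reconstruct(y, op, cfg)
  expect_identical(r1$image, r2$image)
})
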