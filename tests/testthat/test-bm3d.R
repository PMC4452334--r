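test_that("block distance is the per-pixel mean squared difference", {
  z1 <- matrix(1, 2, 2); z0 <- matrix(0, 2, 2)
  expect_equal(block_distance(z1, z0), 1.0)   # (4 * 1) / 4
  expect_equal(block_distance(z1, z1), 0)
  set.seed(13)
  a <- matrix(rnorm(16), 4, 4); b <- matrix(rnorm(16), 4, 4)
  expect_equal(block_distance(a, b), block_distance(b, a))
  expect_error(block_distance(a, matrix(0, 3, 3)), "equal shape")
})

test_that("block matching groups all candidates on a constant image", {
  img <- matrix(0.7, 24, 24)
  p <- bm3d_params(block_size = 8, step = 4, search_window = 16, max_group = 16)
  grp <- match_blocks(img, c(9, 9), p)
  # grid positions 1,5,9,13,17 per axis, all within the window, all distance 0
  expect_equal(nrow(grp$member_positions), 16L)   # truncated to max_group
  expect_true(all(grp$distances == 0))
  expect_equal(grp$member_positions[1, ], c(9L, 9L))
  p1 <- bm3d_params(block_size = 8, max_group = 1)
  grp1 <- match_blocks(img, c(9, 9), p1)
  expect_equal(nrow(grp1$member_positions), 1L)
  expect_equal(grp1$member_positions[1, ], c(9L, 9L))
  expect_error(match_blocks(img, c(20, 9), p), "inside the image")
})

test_that("matching never crosses textures when the threshold separates them", {
  set.seed(21)
  img <- rbind(matrix(rnorm(16 * 32, 0, 0.01), 16, 32),
               matrix(rnorm(16 * 32, 1, 0.01), 16, 32))
  # cross-texture distance ~ 1, within-texture ~ 2e-4; threshold in between
  p <- bm3d_params(block_size = 8, step = 4, search_window = 32,
                   match_threshold = 0.1, max_group = 64)
  grp_top <- match_blocks(img, c(1, 1), p)
  expect_true(all(grp_top$member_positions[, 1] <= 9))
  grp_bot <- match_blocks(img, c(25, 1), p)
  expect_true(all(grp_bot$member_positions[, 1] >= 17))
})

test_that("lowering the match threshold never grows a group", {
  set.seed(3)
  img <- matrix(rnorm(32 * 32, 0, 0.2), 32, 32)
  sizes <- vapply(c(0.2, 0.1, 0.05, 0.02, 0), function(tau) {
    nrow(match_blocks(img, c(13, 13),
                      bm3d_params(match_threshold = tau))$member_positions)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("collaborative filtering honours the weight rule of the group", {
  p <- bm3d_params(block_size = 4, sigma_denoise = 0.1, hard_threshold = 2.7)
  # all-zero group: everything stays zero, N_har = 0, weight = 1
  zgrp <- structure(list(reference_position = c(1, 1),
                         member_positions = rbind(c(1, 1), c(5, 5)),
                         distances = c(0, 0),
                         stacked_values = array(0, c(4, 4, 2)),
                         weight = NULL, n_nonzero = NULL),
                    class = "block_group")
  zf <- collaborative_filter(zgrp, p)
  expect_true(all(zf$stacked_values == 0))
  expect_equal(zf$n_nonzero, 0L)
  expect_equal(zf$weight, 1)

  # zero threshold: orthonormal round trip, weight 1 / (sigma^2 N_total)
  set.seed(31)
  st <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  grp <- structure(list(reference_position = c(1, 1),
                        member_positions = rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3)),
                        distances = c(0, 0.1, 0.2, 0.3), stacked_values = st,
                        weight = NULL, n_nonzero = NULL),
                   class = "block_group")
  f0 <- collaborative_filter(grp, bm3d_params(block_size = 4,
                                              sigma_denoise = 0.1,
                                              hard_threshold = 0))
  expect_lt(max(abs(f0$stacked_values - st)), 1e-10)
  expect_equal(f0$weight, 1 / (0.1^2 * f0$n_nonzero))
  expect_equal(f0$n_nonzero, 4 * 4 * 4)  # power-of-two stack, all nonzero

  # identical noisy blocks + large threshold: only the common component survives
  set.seed(32)
  blk <- matrix(rnorm(16, 0, 1), 4, 4)
  st_id <- array(rep(blk, 4), c(4, 4, 4))
  gid <- structure(list(reference_position = c(1, 1),
                        member_positions = rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)),
                        distances = rep(0, 4), stacked_values = st_id,
                        weight = NULL, n_nonzero = NULL),
                   class = "block_group")
  fid <- collaborative_filter(gid, bm3d_params(block_size = 4,
                                               sigma_denoise = 100,
                                               hard_threshold = 10))
  for (k in 2:4)
    expect_lt(max(abs(fid$stacked_values[, , k] - fid$stacked_values[, , 1])), 1e-10)
})

test_that("aggregation averages overlapping blocks with their weights", {
  # single group covering the whole image reproduces its filtered values
  v <- matrix(seq_len(16) / 16, 4, 4)
  g1 <- structure(list(reference_position = c(1, 1),
                       member_positions = rbind(c(1, 1)),
                       distances = 0, stacked_values = array(v, c(4, 4, 1)),
                       weight = 2.5, n_nonzero = 16L),
                  class = "block_group")
  expect_equal(aggregate_blocks(list(g1), c(4, 4)), v)
  # equal weights reduce to the plain average of overlapping blocks
  g2 <- g1; g2$member_positions <- rbind(c(1, 1)); g2$stacked_values[] <- 1
  out <- aggregate_blocks(list(g1, g2), c(4, 4))
  expect_equal(out, (v + 1) / 2)
  # uncovered pixels violate the precondition
  g3 <- g1; g3$member_positions <- rbind(c(1, 1))
  expect_error(aggregate_blocks(list(g3), c(8, 8)), "uncovered")
})

test_that("constants pass through the full BM3D pipeline unchanged", {
  for (p in list(bm3d_params(),
                 bm3d_params(sigma_denoise = 0.3, hard_threshold = 5),
                 bm3d_params(block_size = 4, step = 2, max_group = 4,
                             sigma_denoise = 1))) {
    img <- matrix(0.37, 32, 32)
    expect_lt(max(abs(bm3d_denoise(img, p) - img)), 1e-10)
  }
})

test_that("BM3D denoising reduces noise more than a 3x3 mean filter", {
  set.seed(7)
  n <- 128
  ph <- shepp_logan(n)
  noisy <- ph + matrix(rnorm(n * n, 0, 0.05), n, n)
  den <- bm3d_denoise(noisy, bm3d_params(sigma_denoise = 0.05))
  expect_lt(mse(den, ph), mse(noisy, ph))
  mean3 <- matrix(0, n, n)
  padded <- rbind(noisy[1, ], noisy, noisy[n, ])
  padded <- cbind(padded[, 1], padded, padded[, n])
  for (di in 0:2) for (dj in 0:2)
    mean3 <- mean3 + padded[(1:n) + di, (1:n) + dj] / 9
  expect_lt(mse(den, ph), mse(mean3, ph))
})

test_that("BM3D leaves a clean phantom nearly untouched", {
  ph <- shepp_logan(128)
  expect_lt(mse(bm3d_denoise(ph), ph), 1e-4)
})

test_that("BM3D is deterministic", {
  set.seed(9)
  img <- matrix(rnorm(48 * 48, 0.5, 0.1), 48, 48)
  expect_identical(bm3d_denoise(img), bm3d_denoise(img))
})

test_that("the compiled pipeline equals the composed R-level stages", {
  set.seed(17)
  n <- 24
  img <- matrix(rnorm(n * n, 0.5, 0.1), n, n)
  p <- bm3d_params(block_size = 8, step = 4, search_window = 8,
                   match_threshold = 0.05, max_group = 8, sigma_denoise = 0.1)
  refs <- expand.grid(r = seq(1, n - 8 + 1, by = 4), cl = seq(1, n - 8 + 1, by = 4))
  groups <- lapply(seq_len(nrow(refs)), function(i) {
    collaborative_filter(match_blocks(img, c(refs$r[i], refs$cl[i]), p), p)
  })
  r_out <- aggregate_blocks(groups, c(n, n))
  c_out <- bm3d_denoise(img, p)
  expect_lt(max(abs(r_out - c_out)), 1e-8)
})

test_that("the literal indicator-denominator aggregation stays available", {
  set.seed(19)
  img <- matrix(rnorm(32 * 32, 0.5, 0.05), 32, 32)
  w <- bm3d_denoise(img, bm3d_params(sigma_denoise = 0.05))
  l <- bm3d_denoise(img, bm3d_params(sigma_denoise = 0.05, literal_eq11 = TRUE))
  expect_true(all(is.finite(l)))
  expect_false(identical(w, l))
})
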