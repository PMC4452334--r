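test_that("phase wrapping lands in (-pi, pi]", {
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  # sample at pi - 0.1 vs reference at -pi + 0.1 wraps to -0.2, not 2pi - 0.2
  expect_equal(wrap_phase((pi - 0.1) - (-pi + 0.1)), -0.2)
})

test_that("zero-contrast sample reproduces the reference stack bit-identically", {
  z <- matrix(0, 4, 5)
  st <- simulate_phase_stepping(z, z, z, n_steps = 8)
  expect_identical(st$sample, st$reference)
  expect_equal(dim(st$sample), c(8L, 4L, 5L))   # 8 frames per stack
  expect_equal(st$step_positions, (0:7) / 8)
})

test_that("simulator validates its inputs", {
  z <- matrix(0, 2, 2)
  expect_error(simulate_phase_stepping(z, z, z, n_steps = 2), "n_steps")
  expect_error(simulate_phase_stepping(z, z, z, a0_ref = -1), "a0_ref")
  expect_error(simulate_phase_stepping(z, z, z, v_ref = 1.5), "v_ref")
  expect_error(simulate_phase_stepping(z, z, matrix(0, 3, 2)), "same shape")
})

test_that("noiseless simulate -> retrieve round trip is exact", {
  set.seed(42)
  for (ns in c(3L, 8L, 10L)) {
    Tm <- matrix(runif(12, 0, 1), 3, 4)
    S <- matrix(runif(12, 0, 0.5), 3, 4)
    DP <- matrix(runif(12, -2.5, 2.5), 3, 4)
    st <- simulate_phase_stepping(Tm, DP, S, n_steps = ns, a0_ref = 80,
                                  v_ref = 0.4)
    tr <- retrieve_information(st$sample, st$reference)
    expect_lt(max(abs(tr$T - Tm)), 1e-9)
    expect_lt(max(abs(tr$S - S)), 1e-9)
    expect_lt(max(abs(tr$DP - DP)), 1e-9)
  }
})

test_that("single-pixel retrieval recovers DP = pi/4 from a pure sinusoid", {
  one <- matrix(0, 1, 1)
  st <- simulate_phase_stepping(one, matrix(pi / 4, 1, 1), one,
                                n_steps = 10, a0_ref = 100, v_ref = 0.3)
  tr <- retrieve_information(st$sample, st$reference)
  expect_lt(abs(tr$DP[1, 1] - pi / 4), 1e-10)
  expect_equal(tr$fit_reference$a0[1, 1], 100)
  expect_lt(abs(tr$fit_reference$a1[1, 1] / tr$fit_reference$a0[1, 1] - 0.3), 1e-12)
})

test_that("identical stacks retrieve to exactly zero T, S and DP", {
  set.seed(5)
  Tm <- matrix(runif(6), 2, 3); S <- matrix(runif(6, 0, 0.3), 2, 3)
  st <- simulate_phase_stepping(Tm, S * 0, S, n_steps = 6)
  tr <- retrieve_information(st$sample, st$sample)
  expect_true(all(tr$T == 0))
  expect_true(all(tr$S == 0))
  expect_true(all(tr$DP == 0))
})

test_that("nonpositive mean intensity flags pixels instead of crashing", {
  z <- matrix(0, 2, 2)
  st <- simulate_phase_stepping(z, z, z, n_steps = 4, a0_ref = 10, v_ref = 0.2)
  bad <- st$sample; bad[, 1, 1] <- -bad[, 1, 1]
  expect_warning(tr <- retrieve_information(bad, st$reference), "nonpositive")
  expect_true(is.nan(tr$T[1, 1]))
  expect_false(anyNA(tr$T[2, 2]))
})

test_that("Poisson noise is seeded and reproducible", {
  Tm <- matrix(0.2, 3, 3); S <- matrix(0.1, 3, 3); DP <- matrix(0.5, 3, 3)
  a <- simulate_phase_stepping(Tm, DP, S, noise = "poisson", seed = 9,
                               a0_ref = 500)
  b <- simulate_phase_stepping(Tm, DP, S, noise = "poisson", seed = 9,
                               a0_ref = 500)
  expect_identical(a$sample, b$sample)
  # retrieval is still close at high counts
  tr <- retrieve_information(a$sample, a$reference)
  expect_lt(mse(tr$DP, DP), 0.01)
})
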