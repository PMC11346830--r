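test_that("exact generator satisfies the grey difference equation", {
  s <- gm11_sequence(a = -0.05, b = 100, x1 = 80, n = 8)
  z <- mean_sequence(ago(s$value))
  expect_equal(s$value[-1] + (-0.05) * z, rep(100, 7))
  expect_true(all(diff(s$value[-1]) > 0))  # a < 0: increasing from k = 2

  fit <- gm11(s)
  expect_lt(abs(fit$a - (-0.05)), 1e-10)
  expect_lt(abs(fit$b - 100), 1e-8)
})

test_that("flat and degenerate limits behave as documented", {
  flat <- gm11_sequence(a = 0, b = 50, x1 = 50, n = 6)
  expect_equal(flat$value, rep(50, 6))
  expect_error(gm11(flat), class = "greycast_degenerate_error")
  expect_error(gm11_sequence(a = -2, b = 100, x1 = 80, n = 6),
               class = "greycast_degenerate_error")
  expect_error(gm11_sequence(a = -0.05, b = 100, x1 = -1, n = 6),
               class = "greycast_validation_error")
  expect_error(gm11_sequence(a = -0.05, b = 100, x1 = 80, n = 3),
               class = "greycast_validation_error")
})

test_that("noise is seeded, reproducible, and vanishes at noise_sd = 0", {
  exact <- gm11_sequence(a = -0.04, b = 200, x1 = 150, n = 8)
  expect_identical(gm11_simulate(-0.04, 200, 150, 8, noise_sd = 0), exact)
  s1 <- gm11_simulate(-0.04, 200, 150, 8, noise_sd = 0.02, seed = 99)
  s2 <- gm11_simulate(-0.04, 200, 150, 8, noise_sd = 0.02, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(s1$value, exact$value))
  expect_true(all(s1$value > 0))
})

test_that("small multiplicative noise leaves the estimator nearly unbiased", {
  withr::local_seed(5)
  a_hat <- replicate(200, {
    gm11(gm11_simulate(-0.05, 100, 80, 8, noise_sd = 0.01))$a
  })
  expect_lt(abs(mean(a_hat) - (-0.05)), 0.005)
})

test_that("recovery error grows with noise level", {
  grid <- tibble::tibble(a = -0.05, b = 100, x1 = 80, n = 8L,
                         noise_sd = c(0.005, 0.02, 0.08))
  res <- gm11_recovery_experiment(grid, replicates = 100, seed = 21)
  expect_true(all(diff(res$median_abs_err_a) > 0))
})

test_that("recovery experiment is deterministic and exact in the noiseless limit", {
  grid <- tibble::tibble(a = c(-0.08, -0.02), b = 100, x1 = 80, n = 8L,
                         noise_sd = 0)
  res <- gm11_recovery_experiment(grid, replicates = 3, seed = 1)
  expect_lt(max(abs(res$bias_a)), 1e-10)
  expect_equal(res$frac_level1, c(1, 1))

  res2 <- gm11_recovery_experiment(grid, replicates = 3, seed = 1)
  expect_identical(res, res2)

  # replicates = 1 equals a single generate-and-fit call
  one <- gm11_recovery_experiment(
    tibble::tibble(a = -0.05, b = 100, x1 = 80, n = 8L, noise_sd = 0.02),
    replicates = 1, seed = 4
  )
  single <- withr::with_seed(4, gm11(gm11_simulate(-0.05, 100, 80, 8,
                                                   noise_sd = 0.02)))
  expect_equal(one$bias_a, single$a - (-0.05))
  expect_error(gm11_recovery_experiment(replicates = 0),
               class = "greycast_validation_error")
})
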