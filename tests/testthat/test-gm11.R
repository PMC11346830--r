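test_that("least-squares parameters match the published fits to 4 dp", {
  for (i in seq_len(nrow(reference_fits))) {
    ref <- reference_fits[i, ]
    fit <- gm11(builtin_series(ref$indicator))
    expect_equal(round(fit$a, 4), ref$a, info = ref$indicator)
    expect_equal(round(fit$b, 4), ref$b, info = ref$indicator)
  }
})

test_that("exact-recursion series are refit to machine precision", {
  grid <- tidyr::expand_grid(a = c(-0.1, -0.05, 0.02), n = c(5L, 8L, 12L))
  for (i in seq_len(nrow(grid))) {
    series <- gm11_sequence(a = grid$a[i], b = 100, x1 = 80, n = grid$n[i])
    fit <- gm11(series)
    expect_lt(abs(fit$a - grid$a[i]), 1e-10)
    expect_lt(abs(fit$b - 100), 1e-8)
    # the grey difference equation is satisfied with zero residual
    z <- mean_sequence(ago(series$value))
    expect_equal(series$value[-1] + fit$a * z, rep(fit$b, grid$n[i] - 1),
                 tolerance = 1e-9)
    # level-scale fit from the continuous time response tracks the input
    # closely (it is not exact: the discrete recursion and the exponential
    # solution differ at order a^2)
    expect_equal(fit$fitted, series$value, tolerance = 5 * grid$a[i]^2)
  }
})

test_that("normal-equation solution agrees with a generic LS solver", {
  withr::local_seed(7)
  for (i in 1:100) {
    x0 <- random_series()$value
    z <- mean_sequence(ago(x0))
    ne <- greycast:::gm11_normal_equations(z, x0[-1])
    qr_fit <- stats::coef(stats::lm(y ~ z, data = data.frame(z = -z, y = x0[-1])))
    expect_equal(unname(ne[["a"]]), unname(qr_fit[["z"]]), tolerance = 1e-8)
    expect_equal(unname(ne[["b"]]), unname(qr_fit[["(Intercept)"]]),
                 tolerance = 1e-8)
  }
})

test_that("time response starts at the first observation", {
  fit <- gm11(builtin_series("medical_beds"))
  expect_identical(time_response(fit, 0), fit$x1)
  # direct substitution check of the exponential form
  synth <- gm11(gm11_sequence(a = -0.1, b = 10, x1 = 5, n = 6))
  expect_equal(time_response(synth, 1),
               (5 - synth$b / synth$a) * exp(-synth$a) + synth$b / synth$a)
  expect_error(time_response(fit, -1), class = "greycast_validation_error")
})

test_that("predictions keep the first value and grow for negative a", {
  for (name in reference_fits$indicator) {
    fit <- gm11(builtin_series(name))
    pred <- predict(fit, horizon = 3)
    expect_identical(pred$predicted[1], fit$x1)
    expect_equal(nrow(pred), 11)
    expect_equal(pred$year, 2015:2025)
    # a < 0: strictly increasing from the second predicted value onward
    expect_true(all(diff(pred$predicted[-1]) > 0))
  }
  expect_equal(nrow(predict(gm11(builtin_series("pharmacists")), horizon = 0)), 8)
  expect_error(predict(gm11(builtin_series("pharmacists")), horizon = -1),
               class = "greycast_validation_error")
})

test_that("degenerate inputs are rejected", {
  flat <- tibble::tibble(year = 2015:2020, value = rep(100, 6))
  expect_error(gm11(flat), class = "greycast_degenerate_error")
  two_indicators <- jilin_health_resources() |>
    dplyr::filter(indicator %in% c("pharmacists", "medical_beds"))
  expect_error(gm11(two_indicators), class = "greycast_validation_error")
})

test_that("broom methods expose parameters, summary, and residual table", {
  fit <- gm11(builtin_series("registered_nurses"))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate, c(fit$a, fit$b))

  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nobs, 8)
  expect_equal(gl$grade, 1L)

  au <- augment(fit)
  expect_equal(au$.resid, au$value - au$.fitted)
  expect_equal(au$.rel_error_pct[1], 0)
})

test_that("autoplot methods return ggplot objects", {
  fit <- gm11(builtin_series("medical_institutions"))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(gm11_report()$plan), "ggplot")
})
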