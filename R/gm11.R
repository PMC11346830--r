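# GM(1,1): first-order one-variable grey model.
#
# Raw series x0 is accumulated (AGO) to x1; the grey difference equation
#   x0[k] + a * z1[k-1] = b,  k = 2..n,
# with background sequence z1 (neighbour means of x1) is solved for the
# development coefficient a and grey input b by least squares; forecasts come
# from the whitening-equation time response
#   xhat1(k+1) = (x0[1] - b/a) * exp(-a k) + b/a
# followed by first differencing (IAGO).

# Closed-form solution of the 2x2 normal equations for B = [-z, 1], Y = y.
gm11_normal_equations <- function(z, y) {
  m <- length(z)
  szz <- sum(z * z)
  sz <- sum(z)
  szy <- sum(z * y)
  sy <- sum(y)
  det <- m * szz - sz * sz
  if (abs(det) < .Machine$double.eps * m * max(szz, 1)) {
    rlang::abort(
      "Degenerate model: background sequence is constant (flat series).",
      class = "greycast_degenerate_error"
    )
  }
  a <- (sz * sy - m * szy) / det
  b <- (szz * sy - sz * szy) / det
  c(a = a, b = b)
}

# QR-based reference solution of the same least-squares problem.
gm11_qr <- function(z, y) {
  fit <- stats::lm.fit(cbind(a = -z, b = 1), y)
  stats::coef(fit)
}

#' Fit a GM(1,1) grey model to an annual series
#'
#' Estimates the development coefficient `a` and grey input `b` of the
#' first-order one-variable grey model by least squares on the grey
#' difference equation, after accumulating the series (AGO) and forming the
#' equal-weight background sequence.  The solution uses the explicit 2x2
#' normal equations and is cross-checked against a QR factorization; full
#' floating-point precision is retained throughout (rounding is for display
#' only).
#'
#' Negative `a` corresponds to a growing series.  A perfectly flat series
#' makes the normal equations singular and is rejected with a
#' degenerate-model error, as is a fitted `a` of exactly zero (the
#' time-response function divides by `a`).
#'
#' @param data A data frame with columns `year` (consecutive integers) and
#'   `value` (strictly positive), at least 4 rows.  See
#'   [validate_annual_series()].
#' @param indicator Optional label carried into printed and tabulated output.
#' @return An object of class `"gm11"`: a list with elements `a`, `b`
#'   (estimated parameters), `x1` (first observation), `n`, `years`, `actual`,
#'   `fitted`, `data`, and `indicator`.
#' @examples
#' jilin_health_resources() |>
#'   dplyr::filter(indicator == "medical_institutions") |>
#'   gm11()
#' @export
gm11 <- function(data, indicator = NULL) {
  data <- validate_annual_series(data)
  if (is.null(indicator) && "indicator" %in% names(data)) {
    indicator <- unique(data$indicator)
    if (length(indicator) != 1) {
      rlang::abort(
        "`data` contains multiple indicators; fit one at a time (see `gm11_parameter_table()` for the grouped workflow).",
        class = "greycast_validation_error"
      )
    }
  }
  x0 <- as.numeric(data$value)
  z1 <- mean_sequence(ago(x0))
  y <- x0[-1]

  est <- gm11_normal_equations(z1, y)
  ref <- gm11_qr(z1, y)
  scale <- max(abs(est), abs(ref), 1)
  if (max(abs(est - ref)) > 1e-6 * scale) {
    rlang::abort("Normal-equation and QR solutions disagree; the problem is ill-conditioned.",
                 class = "greycast_degenerate_error")
  }
  if (est[["a"]] == 0) {
    rlang::abort("Degenerate model: development coefficient a is exactly zero.",
                 class = "greycast_degenerate_error")
  }

  object <- structure(
    list(
      a = est[["a"]], b = est[["b"]], x1 = x0[1], n = length(x0),
      years = as.integer(data$year), actual = x0,
      indicator = indicator, data = tibble::as_tibble(data[c("year", "value")])
    ),
    class = "gm11"
  )
  object$fitted <- predict_values(object, horizon = 0)
  object
}

#' Time-response function of a fitted GM(1,1) model
#'
#' Evaluates the accumulated prediction
#' `xhat1(k + 1) = (x0[1] - b/a) * exp(-a * k) + b/a` of the whitening
#' equation.  `k = 0` returns the first observation exactly; `k = n - 1` is
#' the last fitted year and larger `k` extrapolates.
#'
#' @param object A fitted `"gm11"` model.
#' @param k Non-negative integer step(s), vectorized.
#' @return Accumulated predictions `xhat1(k + 1)`, same length as `k`.
#' @examples
#' fit <- gm11(data.frame(year = 2015:2020, value = c(10, 12, 15, 18, 22, 27)))
#' time_response(fit, 0:5)
#' @export
time_response <- function(object, k) {
  stopifnot(inherits(object, "gm11"))
  if (any(k < 0)) {
    rlang::abort("`k` must be non-negative.", class = "greycast_validation_error")
  }
  c0 <- object$x1 - object$b / object$a
  c0 * exp(-object$a * k) + object$b / object$a
}

# Level-scale fitted + forecast values: first value is x0[1] exactly, later
# values are first differences of the time response (IAGO).
predict_values <- function(object, horizon) {
  k <- seq_len(object$n + horizon - 1)
  xhat1 <- time_response(object, c(0, k))
  c(object$x1, diff(xhat1))
}

#' Fitted values and forecasts from a GM(1,1) model
#'
#' Returns the within-sample fitted values and, for `horizon > 0`,
#' extrapolated forecasts obtained by inverse accumulation of the
#' time-response function.  The first fitted value always equals the first
#' observation (zero residual by construction).
#'
#' @param object A fitted `"gm11"` model.
#' @param horizon Number of years to forecast beyond the data (default 3).
#' @param ... Unused.
#' @return A tibble with columns `year`, `value` (actual, `NA` for forecast
#'   years), `predicted`, and `type` (`"fitted"` or `"forecast"`).
#' @examples
#' jilin_health_resources() |>
#'   dplyr::filter(indicator == "pharmacists") |>
#'   gm11() |>
#'   predict(horizon = 3)
#' @export
predict.gm11 <- function(object, horizon = 3, ...) {
  if (horizon < 0) {
    rlang::abort("`horizon` must be non-negative.", class = "greycast_validation_error")
  }
  horizon <- as.integer(horizon)
  pred <- predict_values(object, horizon)
  years <- seq(object$years[1], by = 1L, length.out = object$n + horizon)
  tibble::tibble(
    year = years,
    value = c(object$actual, rep(NA_real_, horizon)),
    predicted = pred,
    type = rep(c("fitted", "forecast"), c(object$n, horizon))
  )
}

#' @export
fitted.gm11 <- function(object, ...) object$fitted

#' @export
residuals.gm11 <- function(object, ...) object$actual - object$fitted

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model",
      if (!is.null(x$indicator)) paste0(" - ", x$indicator), "\n", sep = "")
  cat(sprintf("  years: %d-%d (n = %d)\n", x$years[1], x$years[x$n], x$n))
  cat(sprintf("  development coefficient a = %.4f\n", x$a))
  cat(sprintf("  grey input             b = %.4f\n", x$b))
  d <- gm11_diagnostics(x)
  cat(sprintf("  C = %.4f, P = %.3f, accuracy: level %d (%s)\n",
              d$C, d$P, d$grade, d$grade_label))
  invisible(x)
}
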