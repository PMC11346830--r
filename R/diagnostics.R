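# Residual-based adequacy testing for GM(1,1) fits.
#
# The posterior error ratio C compares the dispersion of the residuals with
# the dispersion of the original series; the small-error probability P is the
# fraction of residuals within 0.6745 original-series standard deviations of
# the mean residual.  Both are computed over all n points, including the
# first year, whose residual is zero by construction.  C is reported on the
# variance scale, C = Var(residuals) / Var(actuals); see the package
# vignette for the calibration of this convention.  (P +, C -) map to a
# four-level accuracy grade; the overall grade is the worse of the two.

grade_labels <- c("Excellent", "Qualified", "Barely qualified", "Unqualified")

# population variance (divide by n); the denominator cancels in C but the
# choice matters for the 0.6745 * S1 band in P
var_n <- function(x) mean((x - mean(x))^2)

#' Relative errors of fitted values
#'
#' Per-year absolute relative error `100 * |actual - fitted| / actual`,
#' in percent.
#'
#' @param actual,fitted Numeric vectors of equal length.
#' @return Numeric vector of percent errors.
#' @examples
#' relative_errors(c(100, 200), c(90, 210))
#' @export
relative_errors <- function(actual, fitted) {
  if (length(actual) != length(fitted)) {
    rlang::abort("`actual` and `fitted` must have equal length.",
                 class = "greycast_validation_error")
  }
  100 * abs(actual - fitted) / actual
}

#' Posterior error ratio C
#'
#' Ratio of the residual variance to the variance of the original series,
#' computed over all points (the first-year residual, zero by construction,
#' included).  Smaller is better; `C = 0` when the fit is exact.
#'
#' @param actual,fitted Numeric vectors of equal length, at least 2 points.
#' @return Scalar `C >= 0`.
#' @examples
#' posterior_error_ratio(c(10, 12, 15, 18), c(10, 12.5, 14.6, 18.2))
#' @export
posterior_error_ratio <- function(actual, fitted) {
  check_residual_input(actual, fitted)
  e <- actual - fitted
  var_n(e) / var_n(actual)
}

#' Small-error probability P
#'
#' Fraction of residuals `e[k]` with `|e[k] - mean(e)| < 0.6745 * S1`, where
#' `S1` is the standard deviation of the original series, computed over all
#' points including the first year.  `P = 1` when every residual is close to
#' the mean residual on the scale of the series' own variability.
#'
#' @param actual,fitted Numeric vectors of equal length, at least 2 points.
#' @return Scalar in `[0, 1]`, a multiple of `1 / n`.
#' @examples
#' small_error_probability(c(10, 12, 15, 18), c(10, 12.5, 14.6, 18.2))
#' @export
small_error_probability <- function(actual, fitted) {
  check_residual_input(actual, fitted)
  e <- actual - fitted
  s1 <- sqrt(var_n(actual))
  mean(abs(e - mean(e)) < 0.6745 * s1)
}

check_residual_input <- function(actual, fitted) {
  if (length(actual) != length(fitted)) {
    rlang::abort("`actual` and `fitted` must have equal length.",
                 class = "greycast_validation_error")
  }
  if (length(actual) < 2) {
    rlang::abort("At least two points are required.",
                 class = "greycast_validation_error")
  }
  if (var_n(actual) == 0) {
    rlang::abort("Degenerate input: the actual series is constant (S1 = 0).",
                 class = "greycast_degenerate_error")
  }
  invisible(NULL)
}

#' Four-level accuracy grade from (C, P)
#'
#' Maps the posterior error ratio and small-error probability each to a
#' level — P: level 1 if `P >= 0.95`, 2 if `P >= 0.80`, 3 if `P >= 0.70`,
#' else 4; C: level 1 if `C <= 0.35`, 2 if `C <= 0.50`, 3 if `C <= 0.65`,
#' else 4 — and returns the worse (numerically larger) of the two as the
#' overall grade.
#'
#' @param C Posterior error ratio, `C >= 0` (vectorized).
#' @param P Small-error probability in `[0, 1]` (vectorized).
#' @return Integer grade 1-4 (1 = Excellent, 2 = Qualified,
#'   3 = Barely qualified, 4 = Unqualified), with labels available as
#'   `gm11_grade_label()`.
#' @examples
#' gm11_grade(C = 0.1535, P = 0.875)  # P limits the grade: level 2
#' gm11_grade(C = 0.0497, P = 1)      # level 1
#' @export
gm11_grade <- function(C, P) {
  stopifnot(all(C >= 0), all(P >= 0 & P <= 1))
  level_p <- 4L - findInterval(P, c(0.70, 0.80, 0.95))
  level_c <- 1L + findInterval(C, c(0.35, 0.50, 0.65), left.open = TRUE)
  pmax(level_p, level_c)
}

#' @rdname gm11_grade
#' @param grade Integer grade 1-4.
#' @export
gm11_grade_label <- function(grade) grade_labels[grade]

#' Applicability flags for a development coefficient
#'
#' Two conventional screens on the fitted development coefficient `a`:
#' the model is *meaningful* when `-2 < a < 2`, and *suitable for
#' medium-term extrapolation* when additionally `a >= -0.3` (growth not too
#' fast for the exponential form to be trusted a few steps ahead; a
#' coefficient outside the meaningful band is never applicable).  Flags are
#' reported, never enforced: forecasting proceeds regardless.
#'
#' @param a Development coefficient(s), finite numeric.
#' @return A tibble with columns `a`, `a_meaningful`, `a_applicable`.
#' @examples
#' applicability(c(-0.0376, -0.5, 2.5))
#' @export
applicability <- function(a) {
  stopifnot(all(is.finite(a)))
  meaningful <- a > -2 & a < 2
  tibble::tibble(
    a = a,
    a_meaningful = meaningful,
    a_applicable = meaningful & a >= -0.3
  )
}

#' Full adequacy report for a fitted GM(1,1) model
#'
#' One-row summary of model adequacy: posterior error ratio `C`, small-error
#' probability `P`, the four-level grade, the maximum within-sample relative
#' error, and the development-coefficient applicability flags.  The per-year
#' residual breakdown is available via [augment.gm11()].
#'
#' @param object A fitted `"gm11"` model.
#' @param max_rel_error_threshold Acceptability threshold (percent) against
#'   which the maximum relative error is reported (default 10); reported,
#'   not enforced.
#' @return A one-row tibble with columns `indicator`, `a`, `b`, `C`, `P`,
#'   `grade`, `grade_label`, `max_rel_error_pct`, `rel_error_acceptable`,
#'   `a_meaningful`, `a_applicable`.
#' @examples
#' jilin_health_resources() |>
#'   dplyr::filter(indicator == "medical_beds") |>
#'   gm11() |>
#'   gm11_diagnostics()
#' @export
gm11_diagnostics <- function(object, max_rel_error_threshold = 10) {
  stopifnot(inherits(object, "gm11"))
  C <- posterior_error_ratio(object$actual, object$fitted)
  P <- small_error_probability(object$actual, object$fitted)
  g <- gm11_grade(C, P)
  rel <- relative_errors(object$actual, object$fitted)
  flags <- applicability(object$a)
  tibble::tibble(
    indicator = object$indicator %||% NA_character_,
    a = object$a, b = object$b,
    C = C, P = P,
    grade = g, grade_label = gm11_grade_label(g),
    max_rel_error_pct = max(rel),
    rel_error_acceptable = max(rel) <= max_rel_error_threshold,
    a_meaningful = flags$a_meaningful,
    a_applicable = flags$a_applicable
  )
}
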