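#' Tidy a GM(1,1) model
#'
#' @param x A fitted `"gm11"` model.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`a`, the development
#'   coefficient, and `b`, the grey input) and columns `term`, `estimate`.
#' @examples
#' fit <- gm11(data.frame(year = 2015:2020, value = c(10, 12, 15, 18, 22, 27)))
#' tidy(fit)
#' @method tidy gm11
#' @export
tidy.gm11 <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' Glance at a GM(1,1) model
#'
#' @param x A fitted `"gm11"` model.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, adequacy statistics
#'   (`C`, `P`, `grade`), maximum relative error, applicability flags,
#'   and `nobs`.
#' @examples
#' fit <- gm11(data.frame(year = 2015:2020, value = c(10, 12, 15, 18, 22, 27)))
#' glance(fit)
#' @method glance gm11
#' @export
glance.gm11 <- function(x, ...) {
  d <- gm11_diagnostics(x)
  tibble::tibble(
    a = x$a, b = x$b, C = d$C, P = d$P,
    grade = d$grade, grade_label = d$grade_label,
    max_rel_error_pct = d$max_rel_error_pct,
    a_meaningful = d$a_meaningful, a_applicable = d$a_applicable,
    nobs = x$n
  )
}

#' Augment data with GM(1,1) fitted values and residuals
#'
#' @param x A fitted `"gm11"` model.
#' @param ... Unused.
#' @return A tibble with one row per fitted year: `year`, `value` (actual),
#'   `.fitted`, `.resid`, and `.rel_error_pct`
#'   (`100 * |actual - fitted| / actual`).
#' @examples
#' fit <- gm11(data.frame(year = 2015:2020, value = c(10, 12, 15, 18, 22, 27)))
#' augment(fit)
#' @method augment gm11
#' @export
augment.gm11 <- function(x, ...) {
  tibble::tibble(
    year = x$years,
    value = x$actual,
    .fitted = x$fitted,
    .resid = x$actual - x$fitted,
    .rel_error_pct = relative_errors(x$actual, x$fitted)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment
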