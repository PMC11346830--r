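#' Round half away from zero
#'
#' Commercial rounding, as used for the display of forecast counts and rates.
#' Unlike [base::round()], which rounds half to even, halves are always moved
#' away from zero, so `round_half_up(0.5) == 1` and `round_half_up(-0.5) == -1`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
#' round_half_up(8.785, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Validate an annual series data frame
#'
#' Checks the contract every modelling function in the package relies on:
#' a `year` column of strictly consecutive integer years, a strictly positive
#' `value` column, and at least `min_length` observations.  Returns the data
#' invisibly so the check can sit inside a pipe.
#'
#' @param data A data frame with columns `year` and `value`.
#' @param min_length Minimum number of rows (default 4, the smallest series
#'   for which a GM(1,1) fit with residual diagnostics is meaningful).
#' @return `data`, invisibly, as a tibble.
#' @examples
#' validate_annual_series(data.frame(year = 2015:2018, value = c(1, 2, 4, 8)))
#' @export
validate_annual_series <- function(data, min_length = 4) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame with columns `year` and `value`.",
                 class = "greycast_validation_error")
  }
  missing_cols <- setdiff(c("year", "value"), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("`data` is missing column(s): ", paste(missing_cols, collapse = ", "), "."),
      class = "greycast_validation_error"
    )
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) < min_length) {
    rlang::abort(
      sprintf("Series has %d row(s); at least %d are required.", nrow(data), min_length),
      class = "greycast_validation_error"
    )
  }
  if (anyNA(data$year) || anyNA(data$value)) {
    bad <- which(is.na(data$year) | is.na(data$value))[1]
    rlang::abort(sprintf("Missing value in row %d.", bad),
                 class = "greycast_validation_error")
  }
  if (any(data$year != round(data$year))) {
    bad <- which(data$year != round(data$year))[1]
    rlang::abort(sprintf("Row %d: year %s is not an integer.", bad, format(data$year[bad])),
                 class = "greycast_validation_error")
  }
  gaps <- which(diff(data$year) != 1)
  if (length(gaps) > 0) {
    rlang::abort(
      sprintf("Years must be consecutive: gap between row %d (%d) and row %d (%d).",
              gaps[1], as.integer(data$year[gaps[1]]),
              gaps[1] + 1L, as.integer(data$year[gaps[1] + 1L])),
      class = "greycast_validation_error"
    )
  }
  nonpos <- which(data$value <= 0)
  if (length(nonpos) > 0) {
    rlang::abort(
      sprintf("Row %d (year %d): value %s is not strictly positive.",
              nonpos[1], as.integer(data$year[nonpos[1]]), format(data$value[nonpos[1]])),
      class = "greycast_validation_error"
    )
  }
  invisible(data)
}
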