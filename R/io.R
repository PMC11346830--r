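#' Read an annual series from CSV
#'
#' Reads a `year,value` CSV into a validated annual-series tibble.  The file
#' must contain strictly consecutive integer years and strictly positive
#' values, with at least four rows; violations raise a validation error that
#' names the offending row.
#'
#' @param path Path to a UTF-8 CSV file with header `year,value`.
#' @return A tibble with integer `year` and double `value`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(dplyr::tibble(year = 2015:2020, value = c(10, 12, 15, 18, 22, 27)), tf)
#' read_series_csv(tf)
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "greycast_io_error")
  }
  data <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_double(),
    value = readr::col_double()
  ))
  validate_annual_series(data)
  dplyr::mutate(data, year = as.integer(.data$year))
}

#' Write a result table to CSV
#'
#' Deterministic, byte-stable CSV output for forecast and plan-comparison
#' tables: fixed column order (as given), `.` decimal separator, no thousands
#' separators.  Numeric columns are written at full precision unless `digits`
#' is supplied, in which case they are rounded half-away-from-zero first.
#'
#' @param table A data frame (e.g. the output of [gm11_forecast_table()] or
#'   [compare_to_plan()]).
#' @param path Output file path.
#' @param digits Optional number of decimal places for numeric columns.
#' @return `table`, invisibly (so the call can end a pipe).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_table_csv(dplyr::tibble(year = 2015, value = 20619), tf)
#' @export
write_table_csv <- function(table, path, digits = NULL) {
  if (!is.data.frame(table)) {
    rlang::abort("`table` must be a data frame.", class = "greycast_validation_error")
  }
  out <- tibble::as_tibble(table)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::where(is.double), ~ round_half_up(.x, digits)
    ))
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Cannot write to %s: %s", path, conditionMessage(e)),
                   class = "greycast_io_error")
    }
  )
  invisible(table)
}
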