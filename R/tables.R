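# Grouped, table-shaped front ends: one GM(1,1) fit per indicator in a long
# data frame, summarised as the parameter/adequacy table, the
# actual-vs-predicted table with forecasts, and the plan-comparison table.

fit_by_indicator <- function(data) {
  validate_long_input(data)
  fits <- data |>
    dplyr::group_by(.data$indicator) |>
    dplyr::group_map(~ gm11(.x, indicator = .y$indicator))
  rlang::set_names(fits, purrr::map_chr(fits, "indicator"))
}

validate_long_input <- function(data) {
  if (!is.data.frame(data) || !all(c("indicator", "year", "value") %in% names(data))) {
    rlang::abort("`data` must have columns `indicator`, `year`, `value`.",
                 class = "greycast_validation_error")
  }
  invisible(data)
}

#' Per-indicator GM(1,1) parameters and adequacy grades
#'
#' Fits one GM(1,1) model per indicator of a long annual-series data frame
#' and returns the parameter estimates with the adequacy diagnostics — the
#' per-indicator analogue of a model-summary table.
#'
#' @param data A data frame with columns `indicator`, `year`, `value`.
#' @param max_rel_error_threshold Passed to [gm11_diagnostics()].
#' @return A tibble with one row per indicator: `indicator`, `a`, `b`, `C`,
#'   `P`, `grade`, `grade_label`, `max_rel_error_pct`, `rel_error_acceptable`,
#'   `a_meaningful`, `a_applicable`.
#' @examples
#' jilin_health_resources() |> gm11_parameter_table()
#' @export
gm11_parameter_table <- function(data, max_rel_error_threshold = 10) {
  fits <- fit_by_indicator(data)
  purrr::map_dfr(fits, gm11_diagnostics,
                 max_rel_error_threshold = max_rel_error_threshold)
}

#' Actual, fitted, and forecast values per indicator
#'
#' Fits one GM(1,1) model per indicator and tabulates actual values, fitted
#' values for the in-sample years with their relative errors, and
#' extrapolated forecasts for `horizon` further years.
#'
#' @param data A data frame with columns `indicator`, `year`, `value`.
#' @param horizon Years to forecast beyond the last observed year (default 3).
#' @return A tibble with columns `indicator`, `year`, `value` (actual; `NA`
#'   for forecast years), `predicted`, `rel_error_pct` (`NA` for forecast
#'   years), and `type`.
#' @examples
#' jilin_health_resources() |> gm11_forecast_table(horizon = 3)
#' @export
gm11_forecast_table <- function(data, horizon = 3) {
  fits <- fit_by_indicator(data)
  purrr::imap_dfr(fits, function(fit, nm) {
    predict(fit, horizon = horizon) |>
      dplyr::mutate(
        indicator = nm,
        rel_error_pct = dplyr::if_else(
          .data$type == "fitted",
          relative_errors(.data$value, .data$predicted),
          NA_real_
        ),
        .before = 1
      ) |>
      dplyr::relocate("indicator", "year", "value", "predicted",
                      "rel_error_pct", "type")
  })
}

#' End-to-end grey-forecast report
#'
#' The full pipeline on a long annual-series data frame: per-indicator
#' GM(1,1) fits with adequacy grading, fitted/forecast values, and — when
#' plan targets are supplied — the 2025 plan-gap comparison.
#'
#' @param data A data frame with columns `indicator`, `year`, `value`.
#'   Defaults to the built-in Jilin Province series.
#' @param targets A plan-target list as returned by [jilin_plan_targets()],
#'   or `NULL` to skip the plan comparison.
#' @param horizon Forecast horizon in years (default 3).
#' @return A list of tibbles: `parameters` (per-indicator parameters and
#'   grades), `forecasts` (actual/fitted/forecast values), and `plan`
#'   (plan comparison, `NULL` if no targets given).
#' @examples
#' rep <- gm11_report()
#' rep$parameters
#' rep$plan
#' @export
gm11_report <- function(data = jilin_health_resources(),
                        targets = jilin_plan_targets(),
                        horizon = 3) {
  parameters <- gm11_parameter_table(data)
  forecasts <- gm11_forecast_table(data, horizon = horizon)
  plan <- NULL
  if (!is.null(targets)) {
    final_year <- max(forecasts$year)
    projected <- forecasts |>
      dplyr::filter(.data$year == final_year) |>
      dplyr::select("indicator", projected = "predicted")
    plan <- compare_to_plan(projected, targets)
  }
  list(parameters = parameters, forecasts = forecasts, plan = plan)
}
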