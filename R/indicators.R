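# Plan-gap indicators: converting forecast head-counts into the rate and
# ratio indicators that 5-year-plan targets are stated in.

#' Rate per thousand population
#'
#' @param count Head-count (persons or beds), non-negative.
#' @param population Population (persons), strictly positive.
#' @return `1000 * count / population`, vectorized.
#' @examples
#' per_thousand(129586, 22343500)
#' @export
per_thousand <- function(count, population) {
  if (any(population <= 0)) {
    rlang::abort("`population` must be positive.",
                 class = "greycast_validation_error")
  }
  1000 * count / population
}

#' Doctor-nurse ratio
#'
#' Nurses per physician, conventionally written `1:r`.
#'
#' @param physicians Number of physicians, strictly positive.
#' @param nurses Number of nurses.
#' @return `r = nurses / physicians`, vectorized.
#' @examples
#' doctor_nurse_ratio(101273, 129586)
#' @export
doctor_nurse_ratio <- function(physicians, nurses) {
  if (any(physicians <= 0)) {
    rlang::abort("`physicians` must be positive.",
                 class = "greycast_validation_error")
  }
  nurses / physicians
}

# How each plan indicator is derived from the forecast head-counts.
# `series` names the forecast series required; `f` maps (counts, population)
# to the indicator value.
plan_indicator_rules <- list(
  beds_per_thousand = list(
    series = "medical_beds",
    f = function(v, pop) per_thousand(v[["medical_beds"]], pop)
  ),
  physicians_total = list(
    series = "licensed_physicians",
    f = function(v, pop) v[["licensed_physicians"]]
  ),
  physicians_per_thousand = list(
    series = "licensed_physicians",
    f = function(v, pop) per_thousand(v[["licensed_physicians"]], pop)
  ),
  nurses_total = list(
    series = "registered_nurses",
    f = function(v, pop) v[["registered_nurses"]]
  ),
  nurses_per_thousand = list(
    series = "registered_nurses",
    f = function(v, pop) per_thousand(v[["registered_nurses"]], pop)
  ),
  doctor_nurse_ratio = list(
    series = c("licensed_physicians", "registered_nurses"),
    f = function(v, pop) doctor_nurse_ratio(v[["licensed_physicians"]],
                                            v[["registered_nurses"]])
  ),
  pharmacists_total = list(
    series = "pharmacists",
    f = function(v, pop) v[["pharmacists"]]
  ),
  pharmacists_per_thousand = list(
    series = "pharmacists",
    f = function(v, pop) per_thousand(v[["pharmacists"]], pop)
  )
)

#' Compare 2025 projections with 5-Year-Plan targets
#'
#' Converts per-indicator forecast head-counts into the indicators the plan
#' targets are stated in (totals, per-thousand-population rates, and the
#' doctor-nurse ratio) and flags each row as met or unmet.  Meeting a target
#' exactly counts as met; comparisons use unrounded values (rounding is for
#' display only).
#'
#' @param forecasts A data frame with columns `indicator` and `projected`
#'   giving the forecast head-count per series (e.g. the final-year rows of
#'   [gm11_forecast_table()]).
#' @param targets A plan-target list as returned by [jilin_plan_targets()]:
#'   `population_2025` plus a `targets` tibble (`indicator`, `target_2025`).
#' @return A tibble of class `"gm11_plan"` with one row per plan indicator:
#'   `indicator`, `target_2025`, `projected_2025`, `met`.  The population
#'   used is attached as attribute `population_2025`.
#' @examples
#' gm11_report()$plan
#' @export
compare_to_plan <- function(forecasts, targets) {
  if (!is.data.frame(forecasts) ||
      !all(c("indicator", "projected") %in% names(forecasts))) {
    rlang::abort("`forecasts` must have columns `indicator` and `projected`.",
                 class = "greycast_validation_error")
  }
  pop <- targets$population_2025
  v <- rlang::set_names(forecasts$projected, forecasts$indicator)

  rows <- purrr::pmap_dfr(targets$targets, function(indicator, target_2025) {
    rule <- plan_indicator_rules[[indicator]]
    if (is.null(rule)) {
      rlang::abort(sprintf("Unknown plan indicator: %s.", indicator),
                   class = "greycast_validation_error")
    }
    missing <- setdiff(rule$series, names(v))
    if (length(missing) > 0) {
      rlang::abort(
        sprintf("Plan indicator %s needs forecast series %s.",
                indicator, paste(missing, collapse = ", ")),
        class = "greycast_validation_error"
      )
    }
    projected <- rule$f(v, pop)
    tibble::tibble(
      indicator = indicator,
      target_2025 = target_2025,
      projected_2025 = projected,
      met = projected >= target_2025
    )
  })
  structure(rows, class = c("gm11_plan", class(rows)),
            population_2025 = pop)
}
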