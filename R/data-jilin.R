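# Built-in Jilin Province health-resource series, 2015-2022, transcribed from
# the provincial statistical yearbook figures.  Values are exact integer counts;
# a checksum test guards the transcription.

jilin_values <- list(
  medical_institutions = c(20619, 20828, 20827, 22648, 22178, 25626, 25345, 25031),
  medical_beds         = c(144695, 151155, 153625, 166743, 170582, 173143, 176306, 176993),
  health_technicians   = c(159103, 166527, 168080, 183327, 188257, 212140, 217215, 217979),
  licensed_physicians  = c(67279, 69613, 70564, 76910, 78741, 85123, 87315, 86661),
  registered_nurses    = c(60742, 65736, 67142, 76140, 78870, 95392, 97803, 98639),
  pharmacists          = c(7903, 7931, 7900, 8139, 8078, 8717, 8894, 8731)
)

#' Jilin Province health-resource series, 2015-2022
#'
#' Annual counts of six health-resource indicators for Jilin Province, China:
#' medical institutions, medical beds, health technicians, licensed
#' (assistant) physicians, registered nurses, and pharmacists.  These short,
#' strictly positive, near-exponential series are the canonical input for a
#' GM(1,1) grey-model fit.
#'
#' @return A tibble with columns `indicator` (character), `year` (integer,
#'   2015-2022) and `value` (integer count), in long format: 6 indicators x
#'   8 years = 48 rows.
#' @examples
#' jilin_health_resources()
#' @export
jilin_health_resources <- function() {
  purrr::imap_dfr(jilin_values, function(v, nm) {
    tibble::tibble(indicator = nm, year = 2015:2022, value = v)
  })
}

#' 14th 5-Year-Plan 2025 targets for Jilin Province
#'
#' The 2025 development targets for health-resource allocation in Jilin
#' Province under the province's 14th 5-Year Plan, together with the projected
#' 2025 permanent population used to convert forecast totals into
#' per-thousand-population rates.  Targets are read from a versioned
#' configuration file shipped with the package; supply `path` to use a
#' different target set.
#'
#' @param path Optional path to a CSV with columns `indicator,target_2025`.
#'   Defaults to the built-in plan file.
#' @param population_2025 Projected 2025 permanent population (persons).
#' @return A list with elements `population_2025` (scalar) and `targets`
#'   (tibble with columns `indicator`, `target_2025`).
#' @examples
#' jilin_plan_targets()
#' @export
jilin_plan_targets <- function(path = NULL, population_2025 = 22343500) {
  if (population_2025 <= 0) {
    rlang::abort("`population_2025` must be positive.",
                 class = "greycast_validation_error")
  }
  if (is.null(path)) {
    path <- system.file("extdata", "plan_targets_2025.csv", package = "greycast",
                        mustWork = TRUE)
  }
  targets <- readr::read_csv(path, col_types = readr::cols(
    indicator = readr::col_character(),
    target_2025 = readr::col_double()
  ))
  if (any(targets$target_2025 <= 0)) {
    rlang::abort("All plan targets must be positive.",
                 class = "greycast_validation_error")
  }
  list(population_2025 = population_2025, targets = targets)
}
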