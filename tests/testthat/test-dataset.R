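test_that("built-in Jilin fixture has the documented shape and values", {
  d <- jilin_health_resources()
  expect_equal(nrow(d), 48)
  expect_setequal(unique(d$year), 2015:2022)
  expect_true(all(d$value > 0))
  expect_equal(dplyr::n_distinct(d$indicator), 6)

  inst <- builtin_series("medical_institutions")
  expect_equal(inst$value[1], 20619)
  expect_equal(inst$value[8], 25031)
  expect_equal(builtin_series("pharmacists")$value,
               c(7903, 7931, 7900, 8139, 8078, 8717, 8894, 8731))

  # transcription checksum over all 48 values
  expect_equal(sum(d$value), 4337935)
})

test_that("plan targets load with population and positive targets", {
  pt <- jilin_plan_targets()
  expect_equal(pt$population_2025, 22343500)
  expect_equal(nrow(pt$targets), 8)
  expect_true(all(pt$targets$target_2025 > 0))
  expect_error(jilin_plan_targets(population_2025 = 0),
               class = "greycast_validation_error")
})

test_that("CSV read/write round trips an annual series", {
  inst <- builtin_series("medical_institutions")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(inst, tf)
  back <- read_series_csv(tf)
  expect_equal(back$year, inst$year)
  expect_equal(back$value, inst$value)
})

test_that("series CSV validation names the offending row", {
  write_csv_tmp <- function(df) {
    tf <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    readr::write_csv(df, tf)
    tf
  }
  expect_error(read_series_csv(tempfile()), class = "greycast_io_error")
  expect_error(
    read_series_csv(write_csv_tmp(
      tibble::tibble(year = 2015:2018, value = c(5, 0, 7, 8)))),
    regexp = "Row 2.*not strictly positive", class = "greycast_validation_error"
  )
  expect_error(
    read_series_csv(write_csv_tmp(
      tibble::tibble(year = c(2015, 2017, 2018, 2019), value = c(5, 6, 7, 8)))),
    regexp = "gap", class = "greycast_validation_error"
  )
  expect_error(
    read_series_csv(write_csv_tmp(
      tibble::tibble(year = 2015:2017, value = c(5, 6, 7)))),
    regexp = "at least 4", class = "greycast_validation_error"
  )
})

test_that("table CSV output is deterministic and handles degenerate tables", {
  tf1 <- withr::local_tempfile(fileext = ".csv")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  tab <- gm11_forecast_table(jilin_health_resources(), horizon = 3)
  write_table_csv(tab, tf1)
  write_table_csv(tab, tf2)
  expect_identical(readLines(tf1), readLines(tf2))

  empty <- tab[0, ]
  tf3 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(empty, tf3)
  expect_length(readLines(tf3), 1)  # header only

  tf4 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tibble::tibble(x = 2.675), tf4, digits = 2)
  expect_match(readLines(tf4)[2], "^2\\.68$")  # half away from zero
})
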