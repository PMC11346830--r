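#' Plot a GM(1,1) fit with its forecast
#'
#' Actual observations as points, the in-sample fit as a solid line, and the
#' extrapolated forecast as a dashed line.
#'
#' @param object A fitted `"gm11"` model.
#' @param horizon Forecast horizon in years (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' jilin_health_resources() |>
#'   dplyr::filter(indicator == "registered_nurses") |>
#'   gm11() |>
#'   ggplot2::autoplot(horizon = 3)
#' @method autoplot gm11
#' @export
autoplot.gm11 <- function(object, horizon = 3, ...) {
  pred <- predict(object, horizon = horizon)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted, linetype = .data$type),
                       colour = "steelblue") +
    ggplot2::geom_point(data = dplyr::filter(pred, !is.na(.data$value)),
                        ggplot2::aes(y = .data$value)) +
    ggplot2::scale_linetype_manual(
      values = c(fitted = "solid", forecast = "dashed"), name = NULL) +
    ggplot2::labs(
      title = paste0("GM(1,1) fit",
                     if (!is.null(object$indicator))
                       paste0(": ", object$indicator)),
      subtitle = sprintf("a = %.4f, b = %.4f", object$a, object$b),
      x = "Year", y = "Value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a plan comparison
#'
#' Dumbbell-style view of plan targets against model projections, one row
#' per plan indicator, coloured by whether the target is met.  Totals and
#' per-thousand rates live on very different scales, so panels are
#' free-scaled by indicator type.
#'
#' @param object A `"gm11_plan"` tibble from [compare_to_plan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(gm11_report()$plan)
#' @method autoplot gm11_plan
#' @export
autoplot.gm11_plan <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      scale_group = dplyr::if_else(.data$target_2025 > 100,
                                   "totals (persons)", "rates and ratios"),
      indicator = factor(.data$indicator, levels = rev(.data$indicator))
    )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$indicator)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$target_2025,
                                       xend = .data$projected_2025,
                                       yend = .data$indicator),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$target_2025), shape = 1, size = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$projected_2025, colour = .data$met),
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick"),
                                 name = "target met") +
    ggplot2::facet_wrap(~scale_group, scales = "free_x") +
    ggplot2::labs(x = "2025 value (open circle = target, filled = projection)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
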