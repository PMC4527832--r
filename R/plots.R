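#' Plot a habitat summary as stacked category lengths
#'
#' Stacked bars of stream length per management unit, split into the four
#' exclusive categories (suitable, too warm only, too acidic only, both
#' stressors). The `TOTAL` row is dropped.
#'
#' @param object A `habitat_summary` from [summarize_habitat()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.habitat_summary <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$unit != "TOTAL") |>
    dplyr::transmute(
      unit = .data$unit,
      suitable = .data$suitable_km,
      `warm only` = .data$warm_km - .data$both_km,
      `acidic only` = .data$acidic_km - .data$both_km,
      both = .data$both_km
    ) |>
    tidyr::pivot_longer(-"unit", names_to = "category",
                        values_to = "length_km") |>
    dplyr::mutate(category = factor(.data$category,
                                    c("suitable", "warm only",
                                      "acidic only", "both")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$length_km,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      suitable = "#3182bd", `warm only` = "#fdae6b",
      `acidic only` = "#de2d26", both = "#756bb1"
    )) +
    ggplot2::labs(x = NULL, y = "stream length (km)", fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot the recalibration mapping
#'
#' The fitted monotone raw-to-corrected mapping with the identity line and
#' the pivot marked.
#'
#' @param object A `recalibration_spec`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.recalibration_spec <- function(object, ...) {
  ggplot2::ggplot(object$knots, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$pivot, linetype = "dotted") +
    ggplot2::geom_line(colour = "#3182bd") +
    ggplot2::labs(x = "raw ANC prediction (ueq/L)",
                  y = "recalibrated ANC (ueq/L)") +
    ggplot2::theme_minimal()
}

#' Histogram of site coupling slopes
#'
#' Distribution of per-site air-water coupling slopes with the
#' high/low-sensitivity threshold marked.
#'
#' @param site_betas Tibble with a `beta` column (e.g. from
#'   [estimate_site_betas()]).
#' @param threshold Sensitivity threshold to mark (default 0.275).
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(site_betas, threshold = 0.275) {
  ggplot2::ggplot(site_betas, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "#3182bd", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "#de2d26") +
    ggplot2::labs(x = "air-water coupling slope (degrees C per degree C)",
                  y = "sites") +
    ggplot2::theme_minimal()
}
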