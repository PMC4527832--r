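#' Habitat suitability thresholds
#'
#' Dual thresholds delimiting habitat for acid-sensitive coldwater species:
#' a reach is thermally suitable strictly below `t_max_c` (default 20,
#' sensitivity variants 18 and 22) and chemically suitable strictly above
#' `anc_min_ueq_l` (default 50). Boundary-equal values are unsuitable:
#' suitability requires strict inequalities, and ties must resolve
#' deterministically.
#'
#' @param t_max_c Thermal threshold in degrees C (sane range 5-35).
#' @param anc_min_ueq_l ANC threshold in ueq/L (positive).
#' @return A list of class `habitat_thresholds`.
#' @export
habitat_thresholds <- function(t_max_c = 20, anc_min_ueq_l = 50) {
  if (t_max_c < 5 || t_max_c > 35) {
    abort("`t_max_c` outside the plausible 5-35 degree C range.")
  }
  if (anc_min_ueq_l <= 0) abort("`anc_min_ueq_l` must be positive.")
  structure(list(t_max_c = t_max_c, anc_min_ueq_l = anc_min_ueq_l),
            class = "habitat_thresholds")
}

#' Classify a reach against the dual thresholds
#'
#' Partitions every (temperature, ANC) pair into exactly one of four
#' categories: `suitable` (T below the thermal threshold and ANC above the
#' acidity threshold), `warm` (thermally unsuitable only), `acidic`
#' (chemically unsuitable only), `both` (the overlap of the two stressors).
#'
#' @param jmmst_c Numeric temperature vector (degrees C).
#' @param anc_ueq_l Numeric ANC vector (ueq/L).
#' @param thresholds A [habitat_thresholds()].
#' @return Character vector over `{"suitable", "warm", "acidic", "both"}`.
#' @examples
#' classify_habitat(c(19, 21, 19, 21), c(60, 60, 40, 40),
#'                  habitat_thresholds())
#' @export
classify_habitat <- function(jmmst_c, anc_ueq_l,
                             thresholds = habitat_thresholds()) {
  if (any(!is.finite(jmmst_c)) || any(!is.finite(anc_ueq_l))) {
    abort("temperature and ANC must be finite.")
  }
  too_warm <- jmmst_c >= thresholds$t_max_c
  too_acidic <- anc_ueq_l <= thresholds$anc_min_ueq_l
  dplyr::case_when(
    too_warm & too_acidic ~ "both",
    too_warm ~ "warm",
    too_acidic ~ "acidic",
    .default = "suitable"
  )
}

#' Habitat accounting by management unit
#'
#' Sums stream length per unit into the standard accounting layout: the
#' thermally unsuitable column (`warm_km`) and the chemically unsuitable
#' column (`acidic_km`) each include the overlap, which is also reported
#' separately (`both_km`), so every row satisfies
#' `warm + acidic - both + suitable = total`. A `TOTAL` row sums the units.
#'
#' @param data Tibble with one row per reach: `reach_id`, `length_km`, unit
#'   columns, plus `jmmst_c` and `anc_ueq_l` (high-ANC gated reaches may
#'   carry `Inf` ANC; any value above the threshold works).
#' @param thresholds A [habitat_thresholds()].
#' @param by `"district"`, `"forest"`, or `"all"`.
#' @return A tibble of class `habitat_summary`: `unit`, `total_km`,
#'   `warm_km`, `warm_pct`, `acidic_km`, `acidic_pct`, `both_km`,
#'   `both_pct`, `suitable_km`, `suitable_pct`. Percentages are of unit
#'   total length (0-100); empty units yield zero rows without division
#'   errors.
#' @export
summarize_habitat <- function(data, thresholds = habitat_thresholds(),
                              by = c("district", "forest", "all")) {
  by <- match.arg(by)
  categories <- tibble::tibble(
    reach_id = data$reach_id,
    category = classify_habitat(data$jmmst_c, data$anc_ueq_l, thresholds)
  )
  long <- length_by_category(data, categories, by = by)
  wide <- long |>
    tidyr::pivot_wider(names_from = "category", values_from = "length_km",
                       values_fill = 0)
  for (cat in c("suitable", "warm", "acidic", "both")) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0
  }
  out <- wide |>
    dplyr::transmute(
      unit = .data$unit,
      total_km = .data$suitable + .data$warm + .data$acidic + .data$both,
      warm_km = .data$warm + .data$both,
      acidic_km = .data$acidic + .data$both,
      both_km = .data$both,
      suitable_km = .data$suitable
    ) |>
    dplyr::mutate(
      warm_pct = pct_of(.data$warm_km, .data$total_km),
      acidic_pct = pct_of(.data$acidic_km, .data$total_km),
      both_pct = pct_of(.data$both_km, .data$total_km),
      suitable_pct = pct_of(.data$suitable_km, .data$total_km)
    ) |>
    dplyr::select("unit", "total_km", "warm_km", "warm_pct", "acidic_km",
                  "acidic_pct", "both_km", "both_pct", "suitable_km",
                  "suitable_pct") |>
    dplyr::arrange(.data$unit != "TOTAL", .data$unit)
  # TOTAL row last
  out <- dplyr::bind_rows(
    dplyr::filter(out, .data$unit != "TOTAL"),
    dplyr::filter(out, .data$unit == "TOTAL")
  )
  structure(out, class = c("habitat_summary", class(out)),
            thresholds = thresholds)
}

pct_of <- function(x, total) ifelse(total > 0, 100 * x / total, 0)

#' Compare habitat summaries between scenarios
#'
#' Computes, per management unit, the change in suitable habitat between a
#' baseline and a future scenario summary as a percentage of total stream
#' length: `100 * (future_suitable - baseline_suitable) / total`.
#'
#' @param baseline,future `habitat_summary` tibbles over the same units.
#' @return Tibble with `unit`, `total_km`, `suitable_km_baseline`,
#'   `suitable_pct_baseline`, `suitable_km_future`, `suitable_pct_future`,
#'   `delta_pct`.
#' @export
compare_scenarios <- function(baseline, future) {
  if (!setequal(baseline$unit, future$unit)) {
    abort("baseline and future summaries cover different units.")
  }
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(baseline), "unit", "total_km",
                  suitable_km_baseline = "suitable_km",
                  suitable_pct_baseline = "suitable_pct"),
    dplyr::select(tibble::as_tibble(future), "unit",
                  suitable_km_future = "suitable_km",
                  suitable_pct_future = "suitable_pct"),
    by = "unit"
  ) |>
    dplyr::mutate(
      delta_pct = pct_of(.data$suitable_km_future - .data$suitable_km_baseline,
                         .data$total_km)
    )
}
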