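#' Validate a dendritic stream network
#'
#' Checks that downstream links form a forest (no cycles), that every
#' non-outlet `downstream_id` resolves to an existing reach, and that
#' contributing area is conserved: at every reach it must equal the sum of
#' incremental areas over the reach and its full upstream closure. A cycle
#' is a hard error (the network is unusable); other issues are reported as
#' diagnostics.
#'
#' @param network A tibble with at least `reach_id`, `downstream_id`,
#'   `incr_area_km2`, `contrib_area_km2`.
#' @param tol Absolute tolerance (km2) for area conservation.
#' @return A tibble of diagnostics with columns `reach_id`, `issue`,
#'   `detail`; zero rows means the network passes.
#' @examples
#' net <- generate_network(generator_config(seed = 1, n_headwaters = 10))
#' nrow(validate_network(net)) == 0
#' @export
validate_network <- function(network, tol = 1e-6) {
  ids <- network$reach_id
  down <- network$downstream_id
  if (anyDuplicated(ids)) abort("duplicate reach_id values in network.")

  # cycle detection: follow downstream pointers with colors
  idx <- match(down, ids)
  state <- integer(length(ids))  # 0 unvisited, 1 in progress, 2 done
  for (s in seq_along(ids)) {
    if (state[s] != 0L) next
    path <- integer(0)
    j <- s
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- idx[j]
    }
    if (!is.na(j) && state[j] == 1L) {
      abort(paste0("cycle detected in downstream links at reach ", ids[j], "."))
    }
    state[path] <- 2L
  }

  issues <- list()
  dangling <- which(!is.na(down) & is.na(idx))
  if (length(dangling)) {
    issues$dangling <- tibble::tibble(
      reach_id = ids[dangling],
      issue = "dangling_link",
      detail = paste0("downstream_id ", down[dangling], " not in network")
    )
  }

  if (all(c("incr_area_km2", "contrib_area_km2") %in% names(network))) {
    expected <- accumulate_area(idx, network$incr_area_km2)
    bad <- which(abs(expected - network$contrib_area_km2) > tol)
    if (length(bad)) {
      issues$area <- tibble::tibble(
        reach_id = ids[bad],
        issue = "area_conservation",
        detail = sprintf("contributing area %.6f != upstream sum %.6f",
                         network$contrib_area_km2[bad], expected[bad])
      )
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(reach_id = integer(), issue = character(), detail = character())
  }
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(slope))` where `a` is contributing area and `slope` the
#' local slope in degrees. Slopes of exactly zero are replaced by 0.001
#' degrees before the tangent to avoid division by zero.
#'
#' @param contributing_area Positive contributing area (caller's units; the
#'   generator passes m2).
#' @param slope_deg Nonnegative slope in degrees.
#' @return Numeric TWI, vectorized over both arguments.
#' @examples
#' compute_twi(exp(1) * tan(10 * pi / 180), 10)  # = 1
#' @export
compute_twi <- function(contributing_area, slope_deg) {
  if (any(contributing_area <= 0)) {
    abort("`contributing_area` must be positive.")
  }
  if (any(slope_deg < 0)) abort("`slope_deg` must be nonnegative.")
  slope_deg <- ifelse(slope_deg == 0, 0.001, slope_deg)
  log(contributing_area / tan(slope_deg * pi / 180))
}

#' Stream length by category and management unit
#'
#' Sums reach lengths within each management unit by habitat (or any other)
#' category, appending a `TOTAL` row equal to the sum over units.
#'
#' @param network A `stream_network` tibble (needs `reach_id`, `length_km`,
#'   and the unit columns).
#' @param categories A tibble with `reach_id` and `category` covering every
#'   reach (an uncovered reach is an error).
#' @param by Unit level: `"district"`, `"forest"`, or `"all"` (one pooled
#'   unit).
#' @return A tibble with columns `unit`, `category`, `length_km`, including
#'   the `TOTAL` row per category.
#' @export
length_by_category <- function(network, categories,
                               by = c("district", "forest", "all")) {
  by <- match.arg(by)
  joined <- dplyr::left_join(
    dplyr::select(as.data.frame(network), "reach_id", "length_km",
                  dplyr::any_of(c("unit_forest", "unit_district"))),
    categories,
    by = "reach_id"
  )
  if (anyNA(joined$category)) {
    missing_ids <- joined$reach_id[is.na(joined$category)]
    abort(paste0("uncategorized reaches: ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) ", ..." else ""))
  }
  joined$unit <- switch(
    by,
    district = joined$unit_district,
    forest = joined$unit_forest,
    all = "ALL"
  )
  per_unit <- joined |>
    dplyr::group_by(.data$unit, .data$category) |>
    dplyr::summarise(length_km = sum(.data$length_km), .groups = "drop")
  totals <- per_unit |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(length_km = sum(.data$length_km), .groups = "drop") |>
    dplyr::mutate(unit = "TOTAL", .before = 1)
  dplyr::bind_rows(per_unit, totals)
}
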