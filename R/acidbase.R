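#' Classify reaches by the high/low ANC gate
#'
#' First step of the two-step ANC estimation: a binomial model scores the
#' probability that a reach's acid neutralizing capacity exceeds the gate
#' (300 ueq/L by default). High-ANC reaches are safely above any biological
#' impairment threshold and receive no downstream level estimate.
#'
#' @param data Covariate tibble with `reach_id`.
#' @param model A [logistic_spec()] scoring P(ANC above the gate); its
#'   `event = "high"` orientation means "above the gate".
#' @return Tibble with `reach_id`, `p_high_anc`, `anc_class` (`"high"` /
#'   `"low"`).
#' @export
classify_anc <- function(data, model) {
  p <- predict(model, data)
  tibble::tibble(
    reach_id = data$reach_id,
    p_high_anc = p,
    anc_class = ifelse(p >= model$cutoff, "high", "low")
  )
}

#' Estimate ANC for low-class reaches
#'
#' Second step: a linear model predicts reach ANC (ueq/L) for reaches the
#' gate classified low. Estimates may be negative (acidified streams carry
#' negative ANC). Passing a reach classified high is an error: the linear
#' level model is parameterized for, and valid on, the low-ANC range only.
#'
#' @param data Covariate tibble for low-class reaches, with `reach_id`; if
#'   an `anc_class` column is present it must be all `"low"`.
#' @param model A `linear_spec` for ANC in ueq/L.
#' @return Tibble with `reach_id`, `anc_raw_ueq_l`.
#' @export
estimate_anc_low <- function(data, model) {
  if ("anc_class" %in% names(data) && any(data$anc_class != "low")) {
    abort("the ANC level model applies to low-class reaches only.")
  }
  tibble::tibble(
    reach_id = data$reach_id,
    anc_raw_ueq_l = predict(model, data)
  )
}

#' Fit a monotone recalibration of ANC predictions
#'
#' The raw level model shows a sign-flipping bias around a pivot (about
#' 75 ueq/L): it over-predicts below and under-predicts above. The
#' recalibration fits an isotonic (monotone nondecreasing) regression of
#' observed on predicted ANC and represents it as piecewise-linear knots,
#' with the pivot inserted as a knot. Isotonic regression minimizes squared
#' error among monotone fits, so on the fitting pairs the corrected
#' predictions can never have larger RMSE than the raw ones; monotonicity
#' guarantees the reach ranking by ANC is preserved, so threshold crossings
#' move coherently.
#'
#' @param predicted,observed Paired numeric vectors (at least 10 pairs, on
#'   both sides of the pivot).
#' @param pivot Pivot value in ueq/L (default 75).
#' @return An object of class `recalibration_spec` with a `knots` tibble
#'   (`x` raw, `y` corrected) and an `identity` flag. If all pairs fall on
#'   one side of the pivot a warning is raised and the identity mapping
#'   returned.
#' @export
fit_recalibration <- function(predicted, observed, pivot = 75) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (length(predicted) < 10) {
    abort("need at least 10 prediction/observation pairs.")
  }
  if (all(predicted > pivot) || all(predicted < pivot)) {
    warn("all predictions on one side of the pivot; returning identity mapping.")
    return(structure(
      list(knots = tibble::tibble(x = range(predicted), y = range(predicted)),
           pivot = pivot, identity = TRUE),
      class = "recalibration_spec"
    ))
  }
  iso <- isoreg(predicted, observed)
  ord <- iso$ord %||% order(predicted)
  x_sorted <- predicted[ord]
  y_fit <- iso$yf
  # collapse tied x to a single knot (mean fitted value; isotonic fits are
  # constant on ties anyway)
  knots <- tibble::tibble(x = x_sorted, y = y_fit) |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$x)
  # enforce nondecreasing y across collapsed knots (guards rounding)
  knots$y <- cummax(knots$y)
  if (pivot > min(knots$x) && pivot < max(knots$x) && !pivot %in% knots$x) {
    y_pivot <- approx(knots$x, knots$y, xout = pivot)$y
    knots <- dplyr::arrange(
      dplyr::bind_rows(knots, tibble::tibble(x = pivot, y = y_pivot)),
      .data$x
    )
  }
  structure(
    list(knots = knots, pivot = pivot, identity = FALSE),
    class = "recalibration_spec"
  )
}

#' @export
print.recalibration_spec <- function(x, ...) {
  cat("<recalibration_spec> ", nrow(x$knots), " knots, pivot ", x$pivot,
      " ueq/L", if (x$identity) " (identity)" else "", "\n", sep = "")
  invisible(x)
}

#' Apply a fitted recalibration to raw ANC predictions
#'
#' Interpolates the piecewise-linear monotone mapping; values beyond the
#' fitted range are mapped by the boundary knot (flat extension), which
#' keeps the mapping nondecreasing everywhere.
#'
#' @param spec A `recalibration_spec` from [fit_recalibration()].
#' @param anc_raw Numeric vector of raw predictions (ueq/L).
#' @return Numeric vector of corrected predictions.
#' @export
apply_recalibration <- function(spec, anc_raw) {
  stopifnot(inherits(spec, "recalibration_spec"))
  if (spec$identity) return(anc_raw)
  approx(spec$knots$x, spec$knots$y, xout = anc_raw, rule = 2)$y
}

#' Two-step ANC estimate for every reach
#'
#' Runs the gate, the level model on low-class reaches, and (optionally)
#' the recalibration, assembling the per-reach ANC table. High-class
#' reaches carry no raw or corrected estimate; their ANC is above the gate
#' and therefore above any impairment threshold.
#'
#' @param data Covariate tibble with `reach_id`.
#' @param gate_model `logistic_spec` for the 300 ueq/L gate.
#' @param level_model `linear_spec` for low-ANC reaches.
#' @param recalibration Optional `recalibration_spec`.
#' @return Tibble with `reach_id`, `anc_class`, `anc_raw_ueq_l`,
#'   `anc_corrected_ueq_l` (both `NA` for high-class reaches; corrected
#'   equals raw when no recalibration is supplied).
#' @export
estimate_anc <- function(data, gate_model, level_model, recalibration = NULL) {
  gate <- classify_anc(data, gate_model)
  out <- dplyr::mutate(gate, anc_raw_ueq_l = NA_real_,
                       anc_corrected_ueq_l = NA_real_)
  low <- out$anc_class == "low"
  if (any(low)) {
    lvl <- estimate_anc_low(data[low, , drop = FALSE], level_model)
    out$anc_raw_ueq_l[low] <- lvl$anc_raw_ueq_l
    out$anc_corrected_ueq_l[low] <- if (is.null(recalibration)) {
      lvl$anc_raw_ueq_l
    } else {
      apply_recalibration(recalibration, lvl$anc_raw_ueq_l)
    }
  }
  dplyr::select(out, "reach_id", "anc_class", "anc_raw_ueq_l",
                "anc_corrected_ueq_l")
}

#' Stratified RMSE of ANC predictions
#'
#' Error magnitudes differ strongly across the ANC range: predictions in
#' the biologically sensitive range are much more accurate than across the
#' full range, so RMSE is reported separately below a split (150 ueq/L by
#' default, on the predicted scale) and overall.
#'
#' @param observed,predicted Paired numeric vectors (ueq/L).
#' @param split Stratification threshold on predictions.
#' @return Tibble with `stratum`, `n`, `rmse`.
#' @export
anc_error_summary <- function(observed, predicted, split = 150) {
  strata <- list(
    below = predicted < split,
    full = rep(TRUE, length(predicted))
  )
  purrr::imap_dfr(strata, function(sel, nm) {
    tibble::tibble(
      stratum = if (nm == "below") paste0("pred < ", split) else "full range",
      n = sum(sel),
      rmse = if (any(sel)) sqrt(mean((observed[sel] - predicted[sel])^2)) else NA_real_
    )
  })
}
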