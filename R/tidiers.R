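#' Tidy a linear model specification
#'
#' @param x A `linear_spec`.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept first): `term`,
#'   `estimate`, `p.value`, `vif`.
#' @exportS3Method generics::tidy
#' @export
tidy.linear_spec <- function(x, ...) {
  terms <- names(x$coefficients)
  tibble::tibble(
    term = c("(Intercept)", terms),
    estimate = c(x$intercept, unname(x$coefficients)),
    p.value = c(NA_real_, if (is.null(x$p_values)) rep(NA_real_, length(terms))
                else unname(x$p_values[terms])),
    vif = c(NA_real_, if (is.null(x$vif)) rep(NA_real_, length(terms))
            else unname(x$vif[terms]))
  )
}

#' Glance at a linear model specification
#'
#' @param x A `linear_spec`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `rmse`, `aic`, `nobs`, `n_terms`,
#'   `search` (`NA` unless the spec came from [select_model()]).
#' @exportS3Method generics::glance
#' @export
glance.linear_spec <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    rmse = x$rmse,
    aic = x$aic %||% NA_real_,
    nobs = x$n %||% NA_integer_,
    n_terms = length(x$coefficients),
    search = x$search %||% NA_character_
  )
}

#' Tidy a logistic model specification
#'
#' @param x A `logistic_spec`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.logistic_spec <- function(x, ...) {
  terms <- names(x$coefficients)
  tibble::tibble(
    term = c("(Intercept)", terms),
    estimate = c(x$intercept, unname(x$coefficients)),
    p.value = c(NA_real_, if (is.null(x$p_values)) rep(NA_real_, length(terms))
                else unname(x$p_values[terms]))
  )
}

#' Glance at a logistic model specification
#'
#' @param x A `logistic_spec`.
#' @param ... Unused.
#' @return One-row tibble: `cutoff`, `event`, `converged`, `separation`,
#'   `nobs`.
#' @exportS3Method generics::glance
#' @export
glance.logistic_spec <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff,
    event = x$event,
    converged = x$converged %||% NA,
    separation = x$separation %||% NA,
    nobs = x$n %||% NA_integer_
  )
}

#' Tidy a recalibration specification
#'
#' @param x A `recalibration_spec`.
#' @param ... Unused.
#' @return The knot tibble (`x` raw prediction, `y` corrected value).
#' @exportS3Method generics::tidy
#' @export
tidy.recalibration_spec <- function(x, ...) {
  x$knots
}
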