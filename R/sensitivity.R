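#' Estimate the air-water coupling slope for one site
#'
#' Ordinary least squares slope of daily maximum stream temperature (MDST)
#' on daily maximum air temperature (MDAT) over a summer series. The slope
#' is the unit change in MDST per 1 degree C change in MDAT.
#'
#' @param data Tibble with columns `mdat_c` and `mdst_c` for a single site.
#' @return A list with `beta`, `intercept`, `r2`, `n`.
#' @examples
#' d <- tibble::tibble(mdat_c = 20:29, mdst_c = 0.5 * (20:29) + 3)
#' estimate_beta(d)$beta  # 0.5
#' @export
estimate_beta <- function(data) {
  mdat <- data$mdat_c
  mdst <- data$mdst_c
  if (length(mdat) < 2 || length(unique(mdat)) < 2) {
    abort("slope undefined: need at least 2 distinct MDAT values.")
  }
  fit <- lm(mdst ~ mdat)
  list(
    beta = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    n = length(mdat)
  )
}

#' Estimate coupling slopes for every site in a long series table
#'
#' @param series Tibble with `site_id`, `mdat_c`, `mdst_c` (long, one row
#'   per site-day).
#' @return Tibble with `site_id`, `beta`, `intercept`, `r2`, `n_days`.
#' @export
estimate_site_betas <- function(series) {
  series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      b <- estimate_beta(d)
      tibble::tibble(beta = b$beta, intercept = b$intercept,
                     r2 = b$r2, n_days = b$n)
    }) |>
    dplyr::ungroup()
}

#' Classify observed thermal sensitivity
#'
#' A site is high-sensitivity when its observed coupling slope is at least
#' the threshold (boundary inclusive), low otherwise.
#'
#' @param beta Numeric vector of observed slopes.
#' @param threshold Slope threshold (default 0.275).
#' @return Character vector, `"high"` or `"low"`.
#' @examples
#' classify_sensitivity(c(0.275, 0.274999, 0.96))
#' @export
classify_sensitivity <- function(beta, threshold = 0.275) {
  if (any(!is.finite(beta))) abort("`beta` must be finite.")
  ifelse(beta >= threshold, "high", "low")
}

#' Construct a logistic model specification
#'
#' Holds logistic-regression coefficients with the probability cutoff used
#' for classification and the orientation of the outcome coding. Fitted
#' specs come from [fit_logistic()]; specs built from published coefficient
#' tables support either orientation via `event` (whether the linear
#' predictor models the probability of the `"high"` or the `"low"` class)
#' and, lacking a published intercept, support contrast checks only.
#'
#' @param coefficients Named numeric slopes.
#' @param intercept Intercept (default 0).
#' @param cutoff Probability cutoff in (0, 1) for classification.
#' @param event Which class the linear predictor scores: `"high"` or
#'   `"low"`.
#' @param ... Extra fields (`converged`, `separation`, `fit`).
#' @return An object of class `logistic_spec`.
#' @export
logistic_spec <- function(coefficients, intercept = 0, cutoff = 0.5,
                          event = c("high", "low"), ...) {
  event <- match.arg(event)
  if (cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1).")
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("`coefficients` must be a fully named numeric vector.")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients, cutoff = cutoff,
         event = event, ...),
    class = "logistic_spec"
  )
}

#' @export
print.logistic_spec <- function(x, ...) {
  cat("<logistic_spec> ", length(x$coefficients), " term(s), cutoff ",
      x$cutoff, ", event = ", x$event, "\n", sep = "")
  for (nm in names(x$coefficients)) {
    cat("  ", format(nm, width = 12), format(x$coefficients[[nm]], digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fit a logistic classification model
#'
#' Maximum-likelihood logistic regression of a binary class label on
#' landscape covariates. Labels may be 0/1 or `"high"`/`"low"`; the class
#' given by `event` is coded 1. Complete or quasi-complete separation is
#' detected (fitted probabilities numerically 0 or 1) and flagged with a
#' warning; coefficients are still reported.
#'
#' @param data Data frame with label and terms.
#' @param response Label column name.
#' @param terms Predictor columns.
#' @param cutoff Classification cutoff stored on the spec.
#' @param event Class coded as 1 (default `"high"`).
#' @return A `logistic_spec` with `p_values`, `converged`, `separation` and
#'   the `glm` fit in `$fit`.
#' @export
fit_logistic <- function(data, response, terms, cutoff = 0.5,
                         event = c("high", "low")) {
  event <- match.arg(event)
  data <- as.data.frame(data)
  lab <- data[[response]]
  if (is.character(lab) || is.factor(lab)) {
    lab <- as.integer(as.character(lab) == event)
  } else {
    lab <- as.integer(lab)
    if (event == "low") lab <- 1L - lab
  }
  if (length(unique(lab)) < 2) {
    abort("both classes must be present to fit the logistic model.")
  }
  data$.y <- lab
  fml <- stats::reformulate(terms, response = ".y")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warn("possible complete separation: fitted probabilities numerically 0 or 1.")
  }
  cf <- coef(fit)
  s <- summary(fit)
  logistic_spec(
    coefficients = cf[terms],
    intercept = unname(cf["(Intercept)"]),
    cutoff = cutoff,
    event = event,
    p_values = s$coefficients[terms, "Pr(>|z|)"],
    converged = fit$converged,
    separation = separation,
    n = nrow(data),
    fit = fit
  )
}

#' Predicted probability of the high class
#'
#' @param object A `logistic_spec`.
#' @param newdata Covariate data frame.
#' @param ... Unused.
#' @return Numeric vector of probabilities that each row is high-class
#'   (orientation-corrected if the spec scores the low class).
#' @export
predict.logistic_spec <- function(object, newdata, ...) {
  terms <- names(object$coefficients)
  missing_terms <- setdiff(terms, names(newdata))
  if (length(missing_terms)) {
    abort(paste0("missing model terms in newdata: ",
                 paste(missing_terms, collapse = ", ")))
  }
  xm <- as.matrix(as.data.frame(newdata)[terms])
  p_event <- plogis(drop(object$intercept + xm %*% object$coefficients[terms]))
  if (object$event == "high") p_event else 1 - p_event
}

#' Classify reaches by predicted thermal sensitivity
#'
#' Applies the logistic gate to per-reach covariates: a reach is
#' high-sensitivity when the predicted probability of the high class is at
#' least the spec's cutoff (boundary inclusive, mirroring the inclusive
#' observed-slope boundary).
#'
#' @param data Covariate tibble with `reach_id`.
#' @param model A `logistic_spec`.
#' @return Tibble with `reach_id`, `p_high`, `sensitivity_class`.
#' @export
classify_sensitivity_predicted <- function(data, model) {
  p <- predict(model, data)
  tibble::tibble(
    reach_id = data$reach_id,
    p_high = p,
    sensitivity_class = ifelse(p >= model$cutoff, "high", "low")
  )
}

#' Per-class and overall classification rates
#'
#' @param truth,predicted Aligned class-label vectors.
#' @return Tibble with one row per class plus an `overall` row; columns
#'   `class`, `n`, `n_correct`, `pct_correct` (0-100 scale).
#' @examples
#' truth <- rep(c("high", "low"), c(160, 31))
#' pred <- c(rep("high", 157), rep("low", 3), rep("low", 10), rep("high", 21))
#' confusion_summary(truth, pred)
#' @export
confusion_summary <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  per_class <- tibble::tibble(class = truth, ok = truth == predicted) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$ok),
                     .groups = "drop")
  overall <- tibble::tibble(class = "overall", n = length(truth),
                            n_correct = sum(truth == predicted))
  dplyr::bind_rows(per_class, overall) |>
    dplyr::mutate(pct_correct = 100 * .data$n_correct / .data$n)
}

#' Fit the continuous coupling-slope model for high-sensitivity sites
#'
#' OLS regression of the observed coupling slope on landscape covariates,
#' restricted by design to high-sensitivity sites: linear models
#' systematically overestimate the slope at weakly coupled sites, so the
#' continuous model is fitted on, and applied to, high-sensitivity reaches
#' only. Any input site with an observed slope below the threshold is an
#' error.
#'
#' @param data Site tibble with observed `beta` and covariate columns.
#' @param terms Predictor columns.
#' @param response Column holding the observed slope (default `"beta"`).
#' @param threshold High-sensitivity threshold (default 0.275).
#' @return A `linear_spec`.
#' @export
fit_beta_model <- function(data, terms, response = "beta", threshold = 0.275) {
  if (any(data[[response]] < threshold)) {
    abort(paste0("low-sensitivity sites (", response, " < ", threshold,
                 ") must be excluded from the slope model."))
  }
  fit_ols(data, response, terms)
}

#' Project future JMMST under an air-warming scenario
#'
#' High-sensitivity reaches warm by `beta_predicted * delta_mdat_c` added
#' to their contemporary JMMST; low-sensitivity reaches are assumed not to
#' warm. Predicted slopes are floored at zero before projection so warming
#' air can never cool a stream.
#'
#' @param data Tibble with `jmmst_c`, `sensitivity_class`, and
#'   `beta_predicted` (required non-missing on high-sensitivity rows).
#' @param delta_mdat_c Nonnegative air-temperature increase (degrees C).
#' @return `data` with columns `jmmst_future_c` and `delta_mdat_c` added.
#' @examples
#' d <- tibble::tibble(jmmst_c = 18, sensitivity_class = "high",
#'                     beta_predicted = 0.42)
#' project_future(d, 4)$jmmst_future_c  # 18 + 1.68
#' @export
project_future <- function(data, delta_mdat_c) {
  if (length(delta_mdat_c) != 1 || is.na(delta_mdat_c) || delta_mdat_c < 0) {
    abort("`delta_mdat_c` must be a single nonnegative number.")
  }
  high <- data$sensitivity_class == "high"
  if (any(high & !is.finite(data$beta_predicted))) {
    abort("high-sensitivity reaches must carry a finite `beta_predicted`.")
  }
  beta <- pmax(data$beta_predicted, 0)
  dplyr::mutate(
    data,
    jmmst_future_c = .data$jmmst_c +
      ifelse(high, beta * delta_mdat_c, 0),
    delta_mdat_c = delta_mdat_c
  )
}
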