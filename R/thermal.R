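#' Construct a linear model specification
#'
#' A `linear_spec` holds an intercept and named slope coefficients together
#' with fit diagnostics. Fitted specs come from [fit_ols()] /
#' [select_model()]; specs can also be built directly from published
#' coefficient tables, in which case the intercept is typically unknown and
#' only prediction *contrasts* (differences between covariate profiles) are
#' meaningful.
#'
#' @param coefficients Named numeric vector of slopes (names are Variable
#'   IDs).
#' @param intercept Intercept; defaults to 0 for contrast-only use.
#' @param r2,rmse,p_values,vif Optional diagnostics.
#' @param ... Further fields stored on the object (e.g. `aic`, `n`).
#' @return An object of class `linear_spec`.
#' @examples
#' jm <- linear_spec(c(JMMAT = 0.8714, WSAREA = 0.0225))
#' @export
linear_spec <- function(coefficients, intercept = 0, r2 = NA_real_,
                        rmse = NA_real_, p_values = NULL, vif = NULL, ...) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("`coefficients` must be a fully named numeric vector.")
  }
  if (!is.na(rmse) && rmse < 0) abort("`rmse` must be nonnegative.")
  structure(
    list(intercept = intercept, coefficients = coefficients, r2 = r2,
         rmse = rmse, p_values = p_values, vif = vif, ...),
    class = "linear_spec"
  )
}

#' @export
print.linear_spec <- function(x, ...) {
  cat("<linear_spec> ", length(x$coefficients), " term(s)\n", sep = "")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  for (nm in names(x$coefficients)) {
    cat("  ", format(nm, width = 12), format(x$coefficients[[nm]], digits = 4),
        "\n", sep = "")
  }
  if (!is.na(x$r2)) cat("  r2 =", format(x$r2, digits = 3),
                        " rmse =", format(x$rmse, digits = 3), "\n")
  invisible(x)
}

# Variance inflation factors from the predictor correlation matrix.
compute_vif <- function(x) {
  if (ncol(x) < 2) return(setNames(rep(1, ncol(x)), colnames(x)))
  r <- stats::cor(x)
  setNames(diag(solve(r)), colnames(x))
}

#' Fit an ordinary least squares model
#'
#' Fits `response ~ terms` by least squares and returns a [linear_spec()]
#' with r-squared, RMSE (root mean squared residual), per-term p-values and
#' variance inflation factors, plus the Gaussian-likelihood AIC used by the
#' subset search.
#'
#' @param data A data frame containing the response and all terms.
#' @param response Name of the response column.
#' @param terms Character vector of predictor columns; empty fits the
#'   intercept-only model.
#' @return A `linear_spec` with fields `aic`, `n` and the underlying `lm`
#'   fit in `$fit`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
#' fit_ols(d, "y", "x")
#' @export
fit_ols <- function(data, response, terms) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(response, terms), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  used <- data[, c(response, terms), drop = FALSE]
  if (anyNA(used)) abort("missing values in response or terms.")
  if (nrow(data) <= length(terms) + 1) {
    abort("need more observations than terms + 1.")
  }
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = response)
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(collinear, collapse = ", ")))
  }
  s <- summary(fit)
  res <- residuals(fit)
  cf <- coef(fit)
  p <- s$coefficients[, "Pr(>|t|)"]
  spec <- linear_spec(
    coefficients = if (length(terms)) cf[terms] else setNames(numeric(0), character(0)),
    intercept = unname(cf["(Intercept)"]),
    r2 = if (length(terms)) s$r.squared else 0,
    rmse = sqrt(mean(res^2)),
    p_values = if (length(terms)) p[terms] else setNames(numeric(0), character(0)),
    vif = if (length(terms)) compute_vif(as.matrix(data[terms])) else NULL,
    aic = AIC(fit),
    n = nrow(data),
    response = response,
    fit = fit
  )
  spec
}

# Fast subset statistics from a precomputed model matrix: coefficients,
# residual sum of squares, per-term p-values and Gaussian AIC (matching
# stats::AIC on the corresponding lm fit).
subset_fit_stats <- function(x, y, cols) {
  xs <- x[, c(1L, cols + 1L), drop = FALSE]
  n <- length(y)
  k <- length(cols)
  qr_x <- qr(xs)
  if (qr_x$rank < ncol(xs)) return(NULL)
  cf <- qr.coef(qr_x, y)
  res <- y - xs %*% cf
  rss <- sum(res^2)
  sigma2 <- rss / (n - k - 1)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- cf / se
  pval <- 2 * pt(abs(tval), df = n - k - 1, lower.tail = FALSE)
  aic <- n * (log(2 * pi) + log(rss / n) + 1) + 2 * (k + 2)
  list(coef = cf, p = pval, aic = aic, rss = rss)
}

#' Best-subset model selection by AIC under a significance constraint
#'
#' Searches subsets of the candidate terms for the minimum-AIC model among
#' *admissible* subsets: a subset is admissible only if every included term
#' is significant at `alpha` when the subset is fitted. The intercept-only
#' model always competes. With at most `exhaustive_limit` candidates every
#' subset is enumerated; above that a forward best-subset search is used and
#' flagged in the result. AIC uses the Gaussian log-likelihood with the
#' variance MLE (the `stats::AIC` convention for `lm`).
#'
#' @param data Data frame with response and candidates.
#' @param response Response column name.
#' @param candidates Character vector of candidate terms (nonempty).
#' @param alpha Per-term significance threshold for admissibility.
#' @param exhaustive_limit Maximum candidate count for exhaustive search.
#' @param max_terms Largest subset size considered.
#' @return A `linear_spec` (refitted via [fit_ols()] on the winning subset)
#'   with an extra `search` field: `"exhaustive"` or `"forward"`. If no
#'   nonempty subset is admissible the intercept-only model is returned with
#'   a warning.
#' @export
select_model <- function(data, response, candidates, alpha = 0.05,
                         exhaustive_limit = 16, max_terms = Inf) {
  if (!length(candidates)) abort("`candidates` must be nonempty.")
  data <- as.data.frame(data)
  y <- data[[response]]
  x <- cbind(`(Intercept)` = 1, as.matrix(data[candidates]))
  n <- length(y)
  p <- length(candidates)

  null_aic <- subset_fit_stats(x, y, integer(0))$aic
  best <- list(cols = integer(0), aic = null_aic)

  if (p <= exhaustive_limit) {
    search <- "exhaustive"
    for (k in seq_len(min(p, max_terms, n - 2))) {
      for (cols in combn_list(p, k)) {
        st <- subset_fit_stats(x, y, cols)
        if (is.null(st)) next
        term_p <- st$p[-1]
        if (all(term_p < alpha) && st$aic < best$aic) {
          best <- list(cols = cols, aic = st$aic)
        }
      }
    }
  } else {
    search <- "forward"
    current <- integer(0)
    repeat {
      if (length(current) >= min(max_terms, n - 2)) break
      remaining <- setdiff(seq_len(p), current)
      step_best <- NULL
      for (j in remaining) {
        st <- subset_fit_stats(x, y, c(current, j))
        if (is.null(st)) next
        if (all(st$p[-1] < alpha) && st$aic < best$aic &&
            (is.null(step_best) || st$aic < step_best$aic)) {
          step_best <- list(cols = c(current, j), aic = st$aic)
        }
      }
      if (is.null(step_best)) break
      current <- step_best$cols
      best <- step_best
    }
  }

  if (!length(best$cols)) {
    warn("no admissible subset improved on the intercept-only model.")
  }
  spec <- fit_ols(data, response, candidates[best$cols])
  spec$search <- search
  spec$candidates <- candidates
  spec
}

combn_list <- function(p, k) {
  m <- combn(p, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Predict from a linear model specification
#'
#' Computes `intercept + sum(coefficient * covariate)` per row. Every model
#' term must be present in `newdata`; for specs built from published
#' coefficients without an intercept, differences between predictions
#' (contrasts) are the meaningful quantity.
#'
#' @param object A `linear_spec`.
#' @param newdata Data frame of covariates.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.linear_spec <- function(object, newdata, ...) {
  terms <- names(object$coefficients)
  missing_terms <- setdiff(terms, names(newdata))
  if (length(missing_terms)) {
    abort(paste0("missing model terms in newdata: ",
                 paste(missing_terms, collapse = ", ")))
  }
  if (!length(terms)) return(rep(object$intercept, nrow(newdata)))
  xm <- as.matrix(as.data.frame(newdata)[terms])
  drop(object$intercept + xm %*% object$coefficients[terms])
}

#' Predict contemporary JMMST over a reach table
#'
#' Applies a fitted (or published-coefficient) JMMST model to per-reach
#' covariates, returning the input with a `jmmst_c` column appended.
#'
#' @param data Covariate tibble (one row per reach).
#' @param model A `linear_spec`.
#' @return `data` with `jmmst_c` added.
#' @export
predict_jmmst <- function(data, model) {
  dplyr::mutate(data, jmmst_c = predict(model, data))
}
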