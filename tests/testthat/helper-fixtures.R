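# Shared fixtures for the test suite. Everything is built in code; the
# regional model coefficients below are the published coefficient sets the
# contrast checks exercise.

# Regional JMMST model slopes (degrees C per covariate unit). No intercept
# is published, so specs built from these support contrasts only.
regional_jmmst_coefs <- function() {
  c(JMMAT = 0.8714, WSAREA = 0.0225, LITHCAR = -0.0727, BFI = -0.0934,
    CCRIP = -0.0508, PPTJUL = 0.0254, LITHSIL = -0.0153)
}

# Regional continuous coupling-slope model (slope units per covariate unit),
# fitted on high-sensitivity sites only.
regional_beta_coefs <- function() {
  c(BFI = -0.0051, WSAREA = 0.0006, LITHSIL = -0.0011, TWI = 0.0721,
    LITHCAR = -0.0024)
}

# A hand-built chain network: reach 1 -> 2 -> ... -> n -> outlet is reach n.
chain_network <- function(lengths_km, incr_km2 = rep(1, length(lengths_km)),
                          unit = "D1") {
  n <- length(lengths_km)
  tibble::tibble(
    reach_id = seq_len(n),
    downstream_id = c(seq_len(n)[-1], NA_integer_),
    length_km = lengths_km,
    incr_area_km2 = incr_km2,
    contrib_area_km2 = cumsum(incr_km2),
    elevation_m = seq(1000, 400, length.out = n),
    unit_forest = "F1",
    unit_district = unit
  )
}

# Reaches whose temperature/ANC values force given exclusive habitat
# categories (one reach per category entry), all in one district.
category_fixture <- function(lengths, categories, unit = "D1") {
  vals <- list(
    suitable = c(t = 15, anc = 200),
    warm = c(t = 25, anc = 200),
    acidic = c(t = 15, anc = 10),
    both = c(t = 25, anc = 10)
  )
  tibble::tibble(
    reach_id = seq_along(lengths),
    length_km = lengths,
    unit_forest = "F1",
    unit_district = unit,
    jmmst_c = purrr::map_dbl(categories, ~ vals[[.x]][["t"]]),
    anc_ueq_l = purrr::map_dbl(categories, ~ vals[[.x]][["anc"]])
  )
}

# Independent brute-force enumeration oracle for the subset search: fits
# every subset with lm(), applies the per-term significance filter, and
# returns the admissible subset with the lowest stats::AIC.
brute_force_select <- function(data, response, candidates, alpha = 0.05) {
  best_terms <- character(0)
  best_aic <- AIC(lm(stats::reformulate("1", response), data = data))
  for (k in seq_along(candidates)) {
    for (j in seq_len(ncol(utils::combn(length(candidates), k)))) {
      terms <- candidates[utils::combn(length(candidates), k)[, j]]
      fit <- lm(stats::reformulate(terms, response), data = data)
      p <- summary(fit)$coefficients[terms, "Pr(>|t|)"]
      if (all(p < alpha) && AIC(fit) < best_aic) {
        best_aic <- AIC(fit)
        best_terms <- terms
      }
    }
  }
  list(terms = sort(best_terms), aic = best_aic)
}
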