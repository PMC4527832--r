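#' Pipeline configuration
#'
#' Bundles the generator configuration with every fixed constant of the
#' vulnerability framework: the habitat thresholds, the warming scenarios,
#' the observed-slope threshold separating high from low thermal
#' sensitivity, the logistic classification cutoff, the ANC gate, and the
#' recalibration pivot. Defaults are the framework's standard constants, so
#' a default run executes the full design at synthetic scale.
#'
#' @param generator A [generator_config()].
#' @param thresholds A [habitat_thresholds()].
#' @param scenarios Nonnegative air-warming deltas in degrees C; must be
#'   nonempty and include 0 (the contemporary baseline).
#' @param beta_threshold Observed-slope threshold for high sensitivity.
#' @param logistic_cutoff Probability cutoff of the sensitivity gate.
#' @param anc_gate ANC gate in ueq/L separating high- from low-ANC reaches.
#' @param recalibration_pivot Pivot (ueq/L) of the bias recalibration.
#' @param thermal_candidates Candidate Variable IDs for the JMMST subset
#'   search.
#' @param sensitivity_terms Terms of the logistic sensitivity gate.
#' @param beta_terms Terms of the continuous slope model.
#' @param anc_gate_terms,anc_level_terms Terms of the ANC gate and level
#'   models.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   every stage output as CSV plus a run log there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            thresholds = habitat_thresholds(),
                            scenarios = c(0, 2, 4),
                            beta_threshold = 0.275,
                            logistic_cutoff = 0.5,
                            anc_gate = 300,
                            recalibration_pivot = 75,
                            thermal_candidates = c("JMMAT", "WSAREA", "LITHCAR",
                                                   "BFI", "CCRIP", "PPTJUL",
                                                   "LITHSIL", "TWI", "SLOPE",
                                                   "EVHRIP"),
                            sensitivity_terms = c("WSAREA", "LITHCAR", "EVHRIP"),
                            beta_terms = c("BFI", "WSAREA", "LITHSIL", "TWI",
                                           "LITHCAR"),
                            anc_gate_terms = c("TANN", "LITHCAR", "BFI"),
                            anc_level_terms = c("TANN", "LITHCAR", "LITHSIL",
                                                "BFI", "PPTANN"),
                            output_dir = NULL) {
  if (!length(scenarios) || !0 %in% scenarios) {
    abort("`scenarios` must be nonempty and include 0 (the baseline).")
  }
  if (any(scenarios < 0)) abort("scenario deltas must be nonnegative.")
  if (anc_gate <= 0 || recalibration_pivot <= 0 || beta_threshold <= 0) {
    abort("thresholds must be positive.")
  }
  if (logistic_cutoff <= 0 || logistic_cutoff >= 1) {
    abort("`logistic_cutoff` must be in (0, 1).")
  }
  structure(
    list(generator = generator, thresholds = thresholds,
         scenarios = sort(unique(scenarios)),
         beta_threshold = beta_threshold, logistic_cutoff = logistic_cutoff,
         anc_gate = anc_gate, recalibration_pivot = recalibration_pivot,
         thermal_candidates = thermal_candidates,
         sensitivity_terms = sensitivity_terms, beta_terms = beta_terms,
         anc_gate_terms = anc_gate_terms, anc_level_terms = anc_level_terms,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full vulnerability pipeline
#'
#' Executes the framework end to end on a synthetic watershed:
#' \enumerate{
#'   \item generate the network, covariates, ANC field and daily series;
#'   \item fit the contemporary JMMST regression (AIC subset selection on
#'     site covariates, response = July mean of daily maximum stream
#'     temperature) and predict JMMST for every reach;
#'   \item estimate per-site coupling slopes, fit the logistic
#'     high/low-sensitivity gate and the continuous slope model on
#'     high-sensitivity sites, then classify every reach and predict its
#'     slope;
#'   \item fit the two-step ANC models on sampled sites (binomial gate at
#'     `anc_gate`, linear level model on low-ANC sites, isotonic
#'     recalibration) and estimate ANC for every reach;
#'   \item project JMMST under each warming scenario and account suitable
#'     habitat length per ranger district and national forest.
#' }
#' Every stochastic draw descends from the generator seed, so a rerun with
#' the same configuration reproduces all data outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `watershed`, `site_data`,
#'   `thermal_model`, `sensitivity_model`, `beta_model`, `anc_gate_model`,
#'   `anc_level_model`, `recalibration`, `reaches` (per-reach table with
#'   predictions, class and ANC), `projections` (per reach x scenario),
#'   `summaries` (per scenario, by district and forest), `comparisons`
#'   (scenario deltas vs baseline), and `log` (per-stage diagnostics).
#'   When `config$output_dir` is set, CSVs and `run_log.txt` are written
#'   there as well.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(generator = generator_config(seed = 1,
#'                                                     n_headwaters = 150,
#'                                                     n_sites = 80))
#' res <- run_pipeline(cfg)
#' res$summaries[["2"]]$forest
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    note(sprintf("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  note("seed ", config$generator$seed)

  ws <- stage("generate", generate_watershed(config$generator))
  network <- ws$network
  covariates <- ws$covariates

  # site table: observed JMMST is the July mean of daily maximum stream temps
  site_data <- stage("sites", {
    july <- dplyr::filter(ws$daily$series, format(.data$date, "%m") == "07")
    jmmst_obs <- july |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(jmmst_obs = mean(.data$mdst_c), .groups = "drop")
    betas <- estimate_site_betas(ws$daily$series)
    ws$daily$sites |>
      dplyr::left_join(jmmst_obs, by = "site_id") |>
      dplyr::left_join(betas, by = "site_id") |>
      dplyr::left_join(covariates, by = c(site_id = "reach_id")) |>
      dplyr::mutate(
        sensitivity_class = classify_sensitivity(.data$beta,
                                                 config$beta_threshold)
      )
  })

  thermal_model <- stage("fit-thermal", {
    select_model(site_data, "jmmst_obs", config$thermal_candidates)
  })
  note("thermal model terms: ",
       paste(names(thermal_model$coefficients), collapse = ", "),
       sprintf(" (r2 = %.3f, rmse = %.2f)", thermal_model$r2,
               thermal_model$rmse))

  sensitivity_model <- stage("fit-gate", {
    fit_logistic(site_data, "sensitivity_class", config$sensitivity_terms,
                 cutoff = config$logistic_cutoff, event = "high")
  })
  gate_pred <- classify_sensitivity_predicted(
    dplyr::rename(site_data, reach_id = "site_id"), sensitivity_model
  )
  cm <- confusion_summary(site_data$sensitivity_class,
                          gate_pred$sensitivity_class)
  note("gate confusion: ",
       paste(sprintf("%s %.1f%%", cm$class, cm$pct_correct), collapse = ", "))

  beta_model <- stage("fit-beta", {
    fit_beta_model(
      dplyr::filter(site_data, .data$sensitivity_class == "high"),
      config$beta_terms, threshold = config$beta_threshold
    )
  })
  note(sprintf("slope model r2 = %.3f, rmse = %.3f", beta_model$r2,
               beta_model$rmse))

  anc_models <- stage("fit-anc", {
    anc_sites <- site_data |>
      dplyr::left_join(ws$anc, by = c(site_id = "reach_id")) |>
      dplyr::mutate(anc_class_obs = ifelse(.data$anc_ueq_l > config$anc_gate,
                                           "high", "low"))
    gate <- fit_logistic(anc_sites, "anc_class_obs", config$anc_gate_terms,
                         cutoff = 0.5, event = "high")
    low_sites <- dplyr::filter(anc_sites, .data$anc_class_obs == "low")
    level <- fit_ols(low_sites, "anc_ueq_l", config$anc_level_terms)
    recal <- fit_recalibration(predict(level, low_sites),
                               low_sites$anc_ueq_l,
                               pivot = config$recalibration_pivot)
    list(gate = gate, level = level, recal = recal)
  })

  reaches <- stage("predict", {
    gate_all <- classify_sensitivity_predicted(covariates, sensitivity_model)
    anc_all <- estimate_anc(covariates, anc_models$gate, anc_models$level,
                            anc_models$recal)
    network |>
      dplyr::left_join(predict_jmmst(covariates, thermal_model) |>
                         dplyr::select("reach_id", "jmmst_c"),
                       by = "reach_id") |>
      dplyr::left_join(gate_all, by = "reach_id") |>
      dplyr::mutate(
        beta_predicted = ifelse(
          .data$sensitivity_class == "high",
          pmax(predict(beta_model, covariates), 0), NA_real_
        )
      ) |>
      dplyr::left_join(anc_all, by = "reach_id") |>
      dplyr::mutate(
        # high-ANC gated reaches are above the gate, hence above any
        # impairment threshold; carry the gate value for classification
        anc_ueq_l = ifelse(.data$anc_class == "high",
                           config$anc_gate + 1,
                           .data$anc_corrected_ueq_l)
      )
  })
  note(sprintf("reaches: %d (%.1f%% high sensitivity)", nrow(reaches),
               100 * mean(reaches$sensitivity_class == "high")))

  scen <- stage("project", {
    purrr::map(config$scenarios, function(delta) {
      proj <- project_future(reaches, delta)
      list(
        delta = delta,
        projection = dplyr::select(proj, "reach_id", "delta_mdat_c",
                                   "jmmst_c", "jmmst_future_c"),
        district = summarize_habitat(
          dplyr::mutate(proj, jmmst_c = .data$jmmst_future_c),
          config$thresholds, by = "district"
        ),
        forest = summarize_habitat(
          dplyr::mutate(proj, jmmst_c = .data$jmmst_future_c),
          config$thresholds, by = "forest"
        )
      )
    }) |> setNames(as.character(config$scenarios))
  })

  baseline <- scen[["0"]]
  comparisons <- purrr::map(
    scen[setdiff(names(scen), "0")],
    function(s) compare_scenarios(baseline$district, s$district)
  )

  result <- structure(
    list(
      config = config,
      watershed = ws,
      site_data = site_data,
      thermal_model = thermal_model,
      sensitivity_model = sensitivity_model,
      beta_model = beta_model,
      anc_gate_model = anc_models$gate,
      anc_level_model = anc_models$level,
      recalibration = anc_models$recal,
      reaches = reaches,
      projections = purrr::map_dfr(scen, "projection"),
      summaries = purrr::map(scen, function(s) s[c("district", "forest")]),
      comparisons = comparisons,
      log = log_lines
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  reaches:", nrow(x$reaches), " sites:", nrow(x$site_data), "\n")
  cat("  scenarios:", paste(x$config$scenarios, collapse = ", "),
      "degrees C\n")
  cat("  thermal model:", paste(names(x$thermal_model$coefficients),
                                collapse = " + "), "\n")
  invisible(x)
}

# Write every data output as CSV plus a plain-text run log. CSVs are the
# deterministic artifacts; the log carries timings and diagnostics.
write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  w(result$watershed$network, "reach_table")
  w(result$watershed$daily$series, "daily_series")
  w(dplyr::select(result$reaches, "reach_id", "p_high",
                  "sensitivity_class", "beta_predicted"),
    "sensitivity_results")
  w(dplyr::select(result$reaches, "reach_id", "anc_class",
                  "anc_raw_ueq_l", "anc_corrected_ueq_l"),
    "anc_results")
  w(result$projections, "projections")
  for (nm in names(result$summaries)) {
    w(tibble::as_tibble(result$summaries[[nm]]$district),
      paste0("habitat_district_delta", nm))
    w(tibble::as_tibble(result$summaries[[nm]]$forest),
      paste0("habitat_forest_delta", nm))
  }
  for (nm in names(result$comparisons)) {
    w(result$comparisons[[nm]], paste0("habitat_change_delta", nm))
  }
  writeLines(c(paste0("run at seed ", result$config$generator$seed),
               result$log),
             file.path(dir, "run_log.txt"))
  invisible(result)
}

#' Read a reach attribute table
#'
#' Reads a reach table CSV as written by the pipeline (`reach_id`,
#' `downstream_id`, `length_km`, `incr_area_km2`, `contrib_area_km2`,
#' `elevation_m`, `unit_forest`, `unit_district`, plus any covariate
#' columns) into a `stream_network` tibble.
#'
#' @param path CSV path.
#' @return A `stream_network` tibble.
#' @export
read_reach_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("stream_network", class(out)))
}

#' Read a daily air/water temperature series table
#'
#' @param path CSV with columns `site_id`, `date` (ISO-8601), `mdat_c`,
#'   `mdst_c`.
#' @return A tibble in long site-day form.
#' @export
read_daily_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}
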