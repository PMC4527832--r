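#' Configuration for the synthetic watershed generator
#'
#' Bundles every tunable of the synthetic-data module: network size and
#' incremental-area targets, the elevation range, the air-temperature lapse
#' used to build JMMAT (July mean daily maximum air temperature), the
#' distribution of air-water coupling slopes, the ANC-elevation profile, and
#' the length of the summer daily series.
#'
#' Defaults emulate a southern Appalachian study landscape: headwater
#' catchments of at least 0.5 km2 with incremental areas averaging about
#' 0.9 km2 (median 0.7), JMMAT tightly and negatively tied to elevation, ANC
#' declining toward high-elevation headwaters, and per-site coupling slopes
#' drawn from a truncated normal with mean 0.42 and SD 0.15 on (0.02, 0.96).
#'
#' @param seed Integer seed; every stochastic draw in the generator is a
#'   deterministic function of it.
#' @param n_headwaters Number of headwater reaches; the binary-merge topology
#'   yields `2 * n_headwaters - 1` reaches in total.
#' @param target_incremental_area_km2 Target mean incremental drainage area.
#' @param target_median_incremental_area_km2 Target median incremental area.
#' @param min_headwater_area_km2 Minimum incremental area for headwater
#'   reaches (smaller draws are rejected).
#' @param elevation_range_m Length-2 numeric, low/high watershed elevation.
#' @param beta_mean,beta_sd,beta_range Mean, SD, and truncation range of the
#'   per-site air-water coupling slope distribution.
#' @param noise_sd_stream_temp_C SD of the daily stream-temperature noise
#'   around the linear air-water relation, in degrees C.
#' @param jmmat_intercept_C,jmmat_elevation_slope,jmmat_noise_sd_C Intercept
#'   (degrees C at 0 m), elevation slope (degrees C per m, negative), and
#'   noise SD of the JMMAT covariate.
#' @param anc_elevation_profile List with elements `intercept_ueq_l`,
#'   `slope_ueq_l_per_m` (negative) and `noise_sd_ueq_l` describing the
#'   monotone-decreasing-with-elevation ANC mean function.
#' @param n_days Number of days in each summer series (June 1 onward).
#' @param n_sites Number of reaches instrumented with temperature loggers.
#' @param n_forests,n_districts_per_forest Management-unit structure: number
#'   of national-forest units and ranger districts nested in each.
#'
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 1, n_headwaters = 50)
#' net <- generate_network(cfg)
#' @export
generator_config <- function(seed = 1L,
                             n_headwaters = 500L,
                             target_incremental_area_km2 = 0.9,
                             target_median_incremental_area_km2 = 0.7,
                             min_headwater_area_km2 = 0.5,
                             elevation_range_m = c(200, 1600),
                             beta_mean = 0.42,
                             beta_sd = 0.15,
                             beta_range = c(0.02, 0.96),
                             noise_sd_stream_temp_C = 1.0,
                             jmmat_intercept_C = 32,
                             jmmat_elevation_slope = -0.0065,
                             jmmat_noise_sd_C = 0.4,
                             anc_elevation_profile = list(
                               intercept_ueq_l = 500,
                               slope_ueq_l_per_m = -0.35,
                               noise_sd_ueq_l = 60
                             ),
                             n_days = 92L,
                             n_sites = 200L,
                             n_forests = 4L,
                             n_districts_per_forest = 3L) {
  if (length(n_headwaters) != 1 || is.na(n_headwaters) || n_headwaters < 1) {
    abort("`n_headwaters` must be a positive count.")
  }
  if (min_headwater_area_km2 <= 0) {
    abort("`min_headwater_area_km2` must be positive.")
  }
  if (target_incremental_area_km2 <= 0 || target_median_incremental_area_km2 <= 0) {
    abort("target incremental areas must be positive.")
  }
  if (length(beta_range) != 2 || beta_range[1] >= beta_range[2] ||
      beta_range[1] < 0 || beta_range[2] > 1) {
    abort("`beta_range` must be an increasing pair within [0, 1].")
  }
  if (n_days < 2) abort("`n_days` must be at least 2.")
  if (length(elevation_range_m) != 2 || elevation_range_m[1] >= elevation_range_m[2]) {
    abort("`elevation_range_m` must be an increasing pair.")
  }
  if (jmmat_elevation_slope >= 0) {
    abort("`jmmat_elevation_slope` must be negative (air cools with elevation).")
  }
  if (anc_elevation_profile$slope_ueq_l_per_m >= 0) {
    abort("ANC must decline with elevation: `slope_ueq_l_per_m` must be negative.")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_headwaters = as.integer(n_headwaters),
      target_incremental_area_km2 = target_incremental_area_km2,
      target_median_incremental_area_km2 = target_median_incremental_area_km2,
      min_headwater_area_km2 = min_headwater_area_km2,
      elevation_range_m = elevation_range_m,
      beta_mean = beta_mean,
      beta_sd = beta_sd,
      beta_range = beta_range,
      noise_sd_stream_temp_C = noise_sd_stream_temp_C,
      jmmat_intercept_C = jmmat_intercept_C,
      jmmat_elevation_slope = jmmat_elevation_slope,
      jmmat_noise_sd_C = jmmat_noise_sd_C,
      anc_elevation_profile = anc_elevation_profile,
      n_days = as.integer(n_days),
      n_sites = as.integer(n_sites),
      n_forests = as.integer(n_forests),
      n_districts_per_forest = as.integer(n_districts_per_forest)
    ),
    class = "generator_config"
  )
}

# Solve lognormal (meanlog, sdlog) so that the half headwater (truncated at
# `min_area`) / half junction mixture hits the target mean and median.
area_lognormal_params <- function(mean_km2, median_km2, min_area) {
  h <- 0.5
  objective <- function(par) {
    mu <- par[1]
    s <- exp(par[2])
    ptail <- plnorm(min_area, mu, s, lower.tail = FALSE)
    if (ptail < 1e-8) return(1e6)
    e_all <- exp(mu + s^2 / 2)
    e_trunc <- e_all * pnorm((mu + s^2 - log(min_area)) / s) / ptail
    mix_mean <- h * e_trunc + (1 - h) * e_all
    cdf <- function(x) {
      tr <- ifelse(x < min_area, 0,
                   (plnorm(x, mu, s) - plnorm(min_area, mu, s)) / ptail)
      h * tr + (1 - h) * plnorm(x, mu, s)
    }
    med <- tryCatch(
      stats::uniroot(function(x) cdf(x) - 0.5,
                     c(min_area / 50, 50 * median_km2))$root,
      error = function(e) NA_real_
    )
    if (is.na(med)) return(1e6)
    (mix_mean - mean_km2)^2 + (med - median_km2)^2
  }
  fit <- stats::optim(c(log(median_km2), log(0.7)), objective)
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# Truncated lognormal sampler via the inverse CDF (exact, no rejection loop).
rlnorm_truncated <- function(n, meanlog, sdlog, lower) {
  p_lo <- plnorm(lower, meanlog, sdlog)
  qlnorm(runif(n, p_lo, 1), meanlog, sdlog)
}

# Truncated normal sampler via the inverse CDF.
rnorm_truncated <- function(n, mean, sd, lower, upper) {
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

#' Generate a synthetic dendritic stream network
#'
#' Builds a rooted binary-merge tree: headwater reaches are merged pairwise
#' (in random order) into junction reaches until a single outlet remains,
#' giving `2 * n_headwaters - 1` reaches. Incremental drainage areas come
#' from a lognormal calibrated so the mixture of truncated headwater draws
#' (at least `min_headwater_area_km2`) and untruncated junction draws has
#' the configured mean and median. Elevation decreases from headwaters to
#' the outlet; contiguous subtrees are labeled as nested management units
#' (national forest / ranger district).
#'
#' @param config A [generator_config()].
#' @return A tibble of class `stream_network` with one row per reach and
#'   columns `reach_id`, `downstream_id` (`NA` at the outlet), `length_km`,
#'   `incr_area_km2`, `contrib_area_km2`, `elevation_m`, `unit_forest`,
#'   `unit_district`.
#' @examples
#' net <- generate_network(generator_config(seed = 2, n_headwaters = 20))
#' validate_network(net)
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_h <- config$n_headwaters
  n_total <- 2L * n_h - 1L

  downstream <- rep(NA_integer_, n_total)
  # random pairwise merging of active subtree roots
  active <- seq_len(n_h)
  next_id <- n_h + 1L
  while (length(active) > 1L) {
    pick <- sample(seq_along(active), 2L)
    downstream[active[pick]] <- next_id
    active <- c(active[-pick], next_id)
    next_id <- next_id + 1L
  }

  params <- area_lognormal_params(
    config$target_incremental_area_km2,
    config$target_median_incremental_area_km2,
    config$min_headwater_area_km2
  )
  incr <- numeric(n_total)
  incr[seq_len(n_h)] <- rlnorm_truncated(
    n_h, params$meanlog, params$sdlog, config$min_headwater_area_km2
  )
  if (n_total > n_h) {
    incr[(n_h + 1L):n_total] <- rlnorm(n_total - n_h, params$meanlog, params$sdlog)
  }

  # mean reach length near 1.6 km, right-skewed as in DEM-derived networks
  length_km <- rlnorm(n_total, log(1.4), 0.5)

  depth <- reach_depths(downstream)
  max_depth <- max(depth)
  rng <- config$elevation_range_m
  elevation <- rng[1] + (rng[2] - rng[1]) * depth / max(max_depth, 1L) +
    rnorm(n_total, 0, 0.01 * (rng[2] - rng[1]))
  elevation <- pmin(pmax(elevation, rng[1]), rng[2])

  contrib <- accumulate_area(downstream, incr)

  units <- assign_units(downstream, config$n_forests, config$n_districts_per_forest)

  structure(
    tibble::tibble(
      reach_id = seq_len(n_total),
      downstream_id = downstream,
      length_km = length_km,
      incr_area_km2 = incr,
      contrib_area_km2 = contrib,
      elevation_m = elevation,
      unit_forest = units$forest,
      unit_district = units$district
    ),
    class = c("stream_network", class(tibble::tibble()))
  )
}

# Number of edges from each reach up from the outlet (outlet depth 0).
reach_depths <- function(downstream) {
  n <- length(downstream)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    path <- integer(0)
    j <- i
    while (is.na(depth[j]) && !is.na(downstream[j])) {
      path <- c(path, j)
      j <- downstream[j]
    }
    base <- if (is.na(downstream[j])) 0L else depth[j]
    if (is.na(depth[j])) depth[j] <- 0L
    if (length(path)) depth[path] <- base + rev(seq_along(path))
  }
  depth[is.na(depth)] <- 0L
  depth
}

# Contributing area by downstream accumulation (children before parents in
# merge order, so a single pass over decreasing depth works).
accumulate_area <- function(downstream, incr) {
  n <- length(downstream)
  contrib <- incr
  ord <- order(reach_depths(downstream), decreasing = TRUE)
  for (i in ord) {
    d <- downstream[i]
    if (!is.na(d)) contrib[d] <- contrib[d] + contrib[i]
  }
  contrib
}

# Subtree sizes (number of reaches upstream of and including each reach).
subtree_sizes <- function(downstream) {
  n <- length(downstream)
  size <- rep(1L, n)
  ord <- order(reach_depths(downstream), decreasing = TRUE)
  for (i in ord) {
    d <- downstream[i]
    if (!is.na(d)) size[d] <- size[d] + size[i]
  }
  size
}

# Contiguous-subtree unit labeling: the outlet plus the (k - 1) largest
# subtree roots become cut points; every reach belongs to its nearest
# cut ancestor. Districts repeat the scheme inside each forest.
assign_units <- function(downstream, n_forests, n_districts) {
  n <- length(downstream)
  size <- subtree_sizes(downstream)
  outlets <- which(is.na(downstream))
  pick_cuts <- function(members, roots, k) {
    pool <- setdiff(members[order(size[members], decreasing = TRUE)], roots)
    c(roots, head(pool, max(k - length(roots), 0L)))
  }
  label_by_cuts <- function(cuts) {
    lab <- rep(NA_integer_, n)
    lab[cuts] <- cuts
    ord <- order(reach_depths(downstream))  # outlet first, then outward
    for (i in ord) {
      if (is.na(lab[i])) lab[i] <- lab[downstream[i]]
    }
    lab
  }
  forest_cuts <- pick_cuts(seq_len(n), outlets, n_forests)
  forest_root <- label_by_cuts(forest_cuts)
  forest_ids <- sort(unique(forest_root))
  forest <- paste0("F", match(forest_root, forest_ids))

  district <- character(n)
  for (f in forest_ids) {
    members <- which(forest_root == f)
    d_cuts <- pick_cuts(members, f, n_districts)
    sub_down <- downstream
    sub_down[f] <- NA_integer_  # treat the unit root as a local outlet
    lab <- label_by_cuts_local(sub_down, members, d_cuts)
    d_ids <- sort(unique(lab))
    district[members] <- paste0(forest[members], "-D", match(lab[members], d_ids))
  }
  list(forest = forest, district = district)
}

label_by_cuts_local <- function(downstream, members, cuts) {
  n <- length(downstream)
  lab <- rep(NA_integer_, n)
  lab[cuts] <- cuts
  ord <- order(reach_depths(downstream))
  for (i in ord) {
    if (i %in% members && is.na(lab[i])) lab[i] <- lab[downstream[i]]
  }
  lab
}

#' Landscape covariate vocabulary
#'
#' Variable IDs of the landscape characteristics used by the statistical
#' models: climate (PPTANN, PPTJUL, TANN, JMMAT, RUNOFF), hydrogeomorphology
#' (WSAREA, SLOPE, BFI, TWI, DRAINDENS), lithology percentages (LITHSIL,
#' LITHARG, LITHFEL, LITHMAF, LITHCAR), soil texture (SOILCLAY), vegetation
#' (FOREST, FORESTRIP, GRASS, GRASSRIP, CC, CCRIP, EVH, EVHRIP) and the
#' solar-radiation family (SOL57 and its cover/height-conditioned variants).
#'
#' @return Character vector of Variable IDs.
#' @export
landscape_variables <- function() {
  c(
    "PPTANN", "PPTJUL", "TANN", "JMMAT", "RUNOFF",
    "WSAREA", "SLOPE", "BFI", "TWI", "DRAINDENS",
    "LITHSIL", "LITHARG", "LITHFEL", "LITHMAF", "LITHCAR",
    "SOILCLAY",
    "FOREST", "FORESTRIP", "GRASS", "GRASSRIP", "CC", "CCRIP", "EVH", "EVHRIP",
    "SOL57", "SOL57FST", "SOL57CC", "SOL57EVH",
    "SOL57RIP", "SOL57FSTRIP", "SOL57CCRIP", "SOL57EVHRIP"
  )
}

#' Generate landscape covariates for every reach
#'
#' Populates the full covariate vocabulary (see [landscape_variables()]) per
#' reach. JMMAT is an affine function of elevation plus small noise, so a
#' regression of JMMAT on elevation recovers a squared correlation near the
#' 0.9 regime typical of mountain air-temperature lapse; lithology shares
#' are drawn from a simplex (five named classes plus an unnamed remainder,
#' so the named shares sum to at most 100); the solar-radiation family is
#' derived from watershed slope and vegetation exactly as its conditioned
#' definitions require (e.g. SOL57CC = SOL57 / CC).
#'
#' @param network A `stream_network` tibble from [generate_network()].
#' @param config The [generator_config()] used to build it.
#' @return A tibble with `reach_id` and one column per Variable ID.
#' @export
generate_covariates <- function(network, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1000L)
  n <- nrow(network)
  elev <- network$elevation_m

  clamp_pct <- function(x) pmin(pmax(x, 0), 100)

  slope_deg <- pmin(pmax(5 + 0.012 * (elev - min(elev)) + rnorm(n, 0, 3), 0.5), 45)
  bfi <- clamp_pct(55 + 10 * rnorm(n))
  twi <- compute_twi(network$contrib_area_km2 * 1e6, slope_deg)
  draindens <- (network$length_km / network$incr_area_km2) / 1000  # m^-1

  # lithology simplex: five named classes plus an unnamed remainder
  alpha <- c(2.0, 1.0, 2.0, 0.5, 0.8, 2.0)
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  shares <- 100 * g / rowSums(g)
  colnames(shares) <- c("LITHSIL", "LITHARG", "LITHFEL", "LITHMAF", "LITHCAR",
                        "other")

  forest <- clamp_pct(85 + 8 * rnorm(n))
  forestrip <- clamp_pct(forest + 3 * rnorm(n))
  grass <- clamp_pct(pmax(0, 100 - forest) * runif(n, 0.2, 0.8))
  grassrip <- clamp_pct(grass * runif(n, 0.5, 1.2))
  cc <- clamp_pct(0.85 * forest + 8 * rnorm(n))
  ccrip <- clamp_pct(cc + 4 * rnorm(n))
  evh <- pmax(1, 22 + 5 * rnorm(n))
  evhrip <- pmax(1, evh + 2 * rnorm(n))

  sol57 <- pmax(1e5, 520000 - 2500 * slope_deg + rnorm(n, 0, 15000))
  sol57rip <- pmax(5e4, 0.8 * sol57 + rnorm(n, 0, 10000))

  safe_div <- function(a, b) a / pmax(b, 1)

  jmmat <- config$jmmat_intercept_C + config$jmmat_elevation_slope * elev +
    rnorm(n, 0, config$jmmat_noise_sd_C)
  pptann <- pmax(0.6, 1.0 + 4e-4 * elev + rnorm(n, 0, 0.08))
  pptjul <- pmax(0.03, 0.08 + 3e-5 * elev + rnorm(n, 0, 0.012))
  tann <- 14 - 0.006 * elev + rnorm(n, 0, 0.5)
  runoff <- pmax(0.1, 0.45 * pptann + rnorm(n, 0, 0.05))

  tibble::tibble(
    reach_id = network$reach_id,
    PPTANN = pptann, PPTJUL = pptjul, TANN = tann, JMMAT = jmmat,
    RUNOFF = runoff,
    WSAREA = network$contrib_area_km2, SLOPE = slope_deg, BFI = bfi,
    TWI = twi, DRAINDENS = draindens,
    LITHSIL = shares[, "LITHSIL"], LITHARG = shares[, "LITHARG"],
    LITHFEL = shares[, "LITHFEL"], LITHMAF = shares[, "LITHMAF"],
    LITHCAR = shares[, "LITHCAR"],
    SOILCLAY = clamp_pct(20 + 8 * rnorm(n)),
    FOREST = forest, FORESTRIP = forestrip, GRASS = grass,
    GRASSRIP = grassrip, CC = cc, CCRIP = ccrip, EVH = evh, EVHRIP = evhrip,
    SOL57 = sol57,
    SOL57FST = safe_div(sol57, forest),
    SOL57CC = safe_div(sol57, cc),
    SOL57EVH = safe_div(sol57, evh),
    SOL57RIP = sol57rip,
    SOL57FSTRIP = safe_div(sol57rip, forestrip),
    SOL57CCRIP = safe_div(sol57rip, ccrip),
    SOL57EVHRIP = safe_div(sol57rip, evhrip)
  )
}

#' Generate paired daily air/water temperature series
#'
#' Samples `n_sites` reaches uniformly as logger sites and simulates, for
#' each, daily maximum air temperature (MDAT) over the summer window and
#' daily maximum stream temperature as
#' `MDST_t = beta * MDAT_t + intercept + noise`. The site coupling slope
#' `beta` is drawn from a truncated normal on `beta_range`; the intercept is
#' `(1 - beta)` times a site groundwater temperature that cools with
#' elevation, so weakly coupled streams track groundwater rather than air.
#' True slopes are returned alongside the series for recovery testing.
#'
#' @param network A `stream_network` tibble.
#' @param config The [generator_config()].
#' @return A list with `series` (tibble: `site_id`, `date`, `mdat_c`,
#'   `mdst_c`) and `sites` (tibble: `site_id`, `beta_true`,
#'   `intercept_true`, `elevation_m`).
#' @export
generate_daily_series <- function(network, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2000L)
  n_sites <- min(config$n_sites, nrow(network))
  site_ids <- sort(sample(network$reach_id, n_sites))
  elev <- network$elevation_m[match(site_ids, network$reach_id)]

  beta <- rnorm_truncated(n_sites, config$beta_mean, config$beta_sd,
                          config$beta_range[1], config$beta_range[2])
  t_gw <- 17 - 0.004 * elev + rnorm(n_sites, 0, 0.8)
  intercept <- (1 - beta) * t_gw

  n_days <- config$n_days
  dates <- seq(as.Date("2012-06-01"), by = "day", length.out = n_days)
  day_frac <- (seq_len(n_days) - 1) / (n_days - 1)
  seasonal <- 4 * sin(pi * day_frac)  # peak mid-summer

  series <- purrr::map2_dfr(seq_len(n_sites), site_ids, function(i, sid) {
    mdat <- (config$jmmat_intercept_C - 2) + config$jmmat_elevation_slope * elev[i] +
      seasonal + rnorm(n_days, 0, 1.8)
    mdst <- beta[i] * mdat + intercept[i] +
      rnorm(n_days, 0, config$noise_sd_stream_temp_C)
    tibble::tibble(site_id = sid, date = dates, mdat_c = mdat, mdst_c = mdst)
  })

  list(
    series = series,
    sites = tibble::tibble(
      site_id = site_ids,
      beta_true = beta,
      intercept_true = intercept,
      elevation_m = elev
    )
  )
}

#' Generate true ANC per reach
#'
#' Acid neutralizing capacity declines linearly with elevation plus noise,
#' reflecting the field gradient in which high-elevation headwaters on
#' base-poor lithologies are the most acid-sensitive. The default profile
#' spans all three strata of interest (< 50, 50-300, > 300 ueq/L); ANC may
#' be negative in acidified headwaters.
#'
#' @param network A `stream_network` tibble.
#' @param config The [generator_config()].
#' @return A tibble with `reach_id` and `anc_ueq_l`.
#' @export
generate_anc_truth <- function(network, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 3000L)
  prof <- config$anc_elevation_profile
  anc <- prof$intercept_ueq_l + prof$slope_ueq_l_per_m * network$elevation_m +
    rnorm(nrow(network), 0, prof$noise_sd_ueq_l)
  tibble::tibble(reach_id = network$reach_id, anc_ueq_l = anc)
}

#' Generate a complete synthetic watershed
#'
#' Convenience wrapper running [generate_network()],
#' [generate_covariates()], [generate_daily_series()] and
#' [generate_anc_truth()] under one configuration.
#'
#' @param config A [generator_config()].
#' @return A list with elements `network`, `covariates`, `daily` (list of
#'   `series` and `sites`) and `anc`.
#' @export
generate_watershed <- function(config) {
  network <- generate_network(config)
  list(
    network = network,
    covariates = generate_covariates(network, config),
    daily = generate_daily_series(network, config),
    anc = generate_anc_truth(network, config)
  )
}
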