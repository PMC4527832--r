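test_that("a single headwater yields a single-reach chain conserving area", {
  cfg <- generator_config(seed = 1, n_headwaters = 1)
  net <- generate_network(cfg)
  expect_equal(nrow(net), 1L)
  expect_true(is.na(net$downstream_id))
  expect_equal(net$contrib_area_km2, net$incr_area_km2)
})

test_that("contributing area equals the brute-force upstream closure sum", {
  cfg <- generator_config(seed = 42, n_headwaters = 40)
  net <- generate_network(cfg)
  upstream_sum <- function(id) {
    members <- id
    repeat {
      parents <- net$reach_id[!is.na(net$downstream_id) &
                                net$downstream_id %in% members]
      new <- setdiff(parents, members)
      if (!length(new)) break
      members <- c(members, new)
    }
    sum(net$incr_area_km2[net$reach_id %in% members])
  }
  for (id in sample(net$reach_id, 12)) {
    expect_equal(net$contrib_area_km2[net$reach_id == id], upstream_sum(id))
  }
})

test_that("network generation is deterministic under a seed and distinct across seeds", {
  cfg <- generator_config(seed = 9, n_headwaters = 30)
  expect_identical(generate_network(cfg), generate_network(cfg))
  other <- generate_network(generator_config(seed = 10, n_headwaters = 30))
  expect_false(identical(generate_network(cfg)$incr_area_km2,
                         other$incr_area_km2))
})

test_that("incremental areas match the target mean and median at scale", {
  net <- generate_network(generator_config(seed = 7, n_headwaters = 5001))
  expect_gt(nrow(net), 10000 - 1)
  expect_lt(abs(mean(net$incr_area_km2) - 0.9), 0.09)  # within 10%
  expect_lt(abs(median(net$incr_area_km2) - 0.7), 0.07)
  hw <- is.na(match(net$reach_id, net$downstream_id))
  expect_true(all(net$incr_area_km2[hw] >= 0.5))
})

test_that("network structure is a forest with valid units", {
  cfg <- generator_config(seed = 3, n_headwaters = 60)
  net <- generate_network(cfg)
  expect_equal(nrow(validate_network(net)), 0L)
  expect_equal(sum(is.na(net$downstream_id)), 1L)  # one outlet
  expect_false(anyNA(net$unit_forest))
  expect_false(anyNA(net$unit_district))
  # districts nest within forests
  nesting <- table(net$unit_district, net$unit_forest) > 0
  expect_true(all(rowSums(nesting) == 1))
})

test_that("JMMAT declines with elevation and explains most of its variance", {
  cfg <- generator_config(seed = 3, n_headwaters = 1000)
  net <- generate_network(cfg)
  covs <- generate_covariates(net, cfg)
  fit <- lm(covs$JMMAT ~ net$elevation_m)
  expect_lt(coef(fit)[2], 0)
  expect_gte(summary(fit)$r.squared, 0.85)

  # monotone construction: zero noise makes the elevation effect exact
  cfg0 <- generator_config(seed = 3, n_headwaters = 20, jmmat_noise_sd_C = 1e-12)
  net0 <- generate_network(cfg0)
  covs0 <- generate_covariates(net0, cfg0)
  two <- order(net0$elevation_m)[c(1, nrow(net0))]
  expect_gt(covs0$JMMAT[two[1]], covs0$JMMAT[two[2]])
})

test_that("covariates respect their ranges and the lithology simplex", {
  cfg <- generator_config(seed = 11, n_headwaters = 300)
  net <- generate_network(cfg)
  covs <- generate_covariates(net, cfg)
  expect_setequal(setdiff(names(covs), "reach_id"), landscape_variables())
  liths <- c("LITHSIL", "LITHARG", "LITHFEL", "LITHMAF", "LITHCAR")
  expect_true(all(rowSums(covs[liths]) <= 100 + 1e-9))
  pct_vars <- c(liths, "SOILCLAY", "FOREST", "FORESTRIP", "GRASS", "GRASSRIP",
                "CC", "CCRIP", "BFI")
  for (v in pct_vars) {
    expect_true(all(covs[[v]] >= 0 & covs[[v]] <= 100), info = v)
  }
})

test_that("daily series encode the configured coupling slopes", {
  cfg <- generator_config(seed = 5, n_headwaters = 40, n_sites = 20,
                          noise_sd_stream_temp_C = 0)
  net <- generate_network(cfg)
  d <- generate_daily_series(net, cfg)
  # noiseless: OLS recovers the stored slope exactly
  for (sid in d$sites$site_id[1:5]) {
    b <- estimate_beta(dplyr::filter(d$series, site_id == sid))
    expect_equal(b$beta, d$sites$beta_true[d$sites$site_id == sid],
                 tolerance = 1e-10)
  }
  expect_true(all(d$sites$beta_true >= cfg$beta_range[1]))
  expect_true(all(d$sites$beta_true <= cfg$beta_range[2]))
})

test_that("drawn slopes match the truncated-normal mean at scale", {
  cfg <- generator_config(seed = 5, n_headwaters = 600, n_sites = 1000)
  d <- generate_daily_series(generate_network(cfg), cfg)
  expect_equal(nrow(d$sites), 1000L)
  expect_lt(abs(mean(d$sites$beta_true) - 0.42), 0.02)
})

test_that("series regeneration under the same seed is identical", {
  cfg <- generator_config(seed = 8, n_headwaters = 25, n_sites = 10)
  net <- generate_network(cfg)
  expect_identical(generate_daily_series(net, cfg),
                   generate_daily_series(net, cfg))
})

test_that("ANC declines with elevation and spans all three strata", {
  cfg <- generator_config(seed = 13, n_headwaters = 1000)
  net <- generate_network(cfg)
  anc <- generate_anc_truth(net, cfg)
  strata <- table(cut(anc$anc_ueq_l, c(-Inf, 50, 300, Inf)))
  expect_true(all(strata > 0))

  cfg0 <- generator_config(
    seed = 13, n_headwaters = 30,
    anc_elevation_profile = list(intercept_ueq_l = 500,
                                 slope_ueq_l_per_m = -0.35,
                                 noise_sd_ueq_l = 0)
  )
  net0 <- generate_network(cfg0)
  anc0 <- generate_anc_truth(net0, cfg0)
  expect_equal(anc0$anc_ueq_l, 500 - 0.35 * net0$elevation_m)
  expect_identical(generate_anc_truth(net0, cfg0),
                   generate_anc_truth(net0, cfg0))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_headwaters = 0), "positive")
  expect_error(generator_config(min_headwater_area_km2 = -1), "positive")
  expect_error(generator_config(beta_range = c(0.5, 1.5)), "within")
  expect_error(generator_config(n_days = 1), "at least 2")
  expect_error(generator_config(jmmat_elevation_slope = 0.01), "negative")
})
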