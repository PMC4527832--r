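test_that("the ANC gate classes match brute-force probability thresholding", {
  set.seed(41)
  spec <- logistic_spec(c(TANN = 0.8), intercept = -8, cutoff = 0.5)
  d <- tibble::tibble(reach_id = 1:50, TANN = runif(50, 5, 15))
  out <- classify_anc(d, spec)
  p_manual <- plogis(-8 + 0.8 * d$TANN)
  expect_equal(out$p_high_anc, p_manual, tolerance = 1e-12)
  expect_equal(out$anc_class, ifelse(p_manual >= 0.5, "high", "low"))
})

test_that("high-class reaches receive no level estimate", {
  gate <- logistic_spec(c(x = 10), intercept = 0, cutoff = 0.5)
  level <- linear_spec(c(x = -50), intercept = 100)
  d <- tibble::tibble(reach_id = 1:4, x = c(-2, -1, 1, 2))
  out <- estimate_anc(d, gate, level)
  expect_equal(out$anc_class, c("low", "low", "high", "high"))
  expect_true(all(is.na(out$anc_raw_ueq_l[out$anc_class == "high"])))
  expect_true(all(!is.na(out$anc_raw_ueq_l[out$anc_class == "low"])))
  # the level model applied directly to a high-class reach is an error
  d_high <- dplyr::mutate(d, anc_class = c("low", "low", "high", "high"))
  expect_error(estimate_anc_low(d_high, level), "low-class reaches only")
})

test_that("level predictions match the dot-product oracle and allow negatives", {
  set.seed(42)
  level <- linear_spec(c(TANN = 20, LITHCAR = 2), intercept = -150)
  d <- tibble::tibble(reach_id = 1:30, TANN = runif(30, 2, 12),
                      LITHCAR = runif(30, 0, 30))
  out <- estimate_anc_low(d, level)
  manual <- -150 + 20 * d$TANN + 2 * d$LITHCAR
  expect_equal(out$anc_raw_ueq_l, manual, tolerance = 1e-12)
  expect_true(any(manual < 0))  # acidified streams have negative ANC

  zero <- linear_spec(c(TANN = 0), intercept = 60)
  expect_equal(estimate_anc_low(d, zero)$anc_raw_ueq_l, rep(60, 30))
})

test_that("recalibration of unbiased pairs is close to the identity", {
  set.seed(43)
  pred <- runif(200, 0, 300)
  obs <- pred + rnorm(200, 0, 5)
  spec <- fit_recalibration(pred, obs)
  grid <- seq(10, 290, by = 10)
  expect_lt(max(abs(apply_recalibration(spec, grid) - grid)), 10)
})

test_that("recalibration undoes a compressive bias about the pivot", {
  set.seed(44)
  truth <- runif(300, -50, 250)
  # biased predictor: compressed by half about 75, i.e. over-predicts below
  # the pivot and under-predicts above it
  pred <- 75 + 0.5 * (truth - 75) + rnorm(300, 0, 3)
  spec <- fit_recalibration(pred, truth)
  corrected <- apply_recalibration(spec, pred)
  rmse <- function(x) sqrt(mean((x - truth)^2))
  expect_lt(rmse(corrected), rmse(pred))
  # round trip recovers the truth scale
  expect_lt(rmse(corrected), 12)
})

test_that("the fitted mapping is nondecreasing and rank preserving", {
  set.seed(45)
  pred <- runif(150, 0, 200)
  obs <- 60 + 0.8 * pred + rnorm(150, 0, 20)
  spec <- fit_recalibration(pred, obs)
  grid <- seq(-50, 250, length.out = 601)
  vals <- apply_recalibration(spec, grid)
  expect_true(all(diff(vals) >= -1e-9))
  # rank order of arbitrary raw values is never inverted
  raw <- runif(100, -20, 220)
  corr <- apply_recalibration(spec, raw)
  ord <- order(raw)
  expect_true(all(diff(corr[ord]) >= -1e-9))
})

test_that("degenerate recalibration inputs are handled explicitly", {
  expect_error(fit_recalibration(1:5, 1:5), "at least 10")
  pred <- seq(100, 200, length.out = 20)  # all above the 75 pivot
  expect_warning(spec <- fit_recalibration(pred, pred + 5), "one side")
  expect_true(spec$identity)
  expect_equal(apply_recalibration(spec, c(80, 150)), c(80, 150))
})

test_that("stratified ANC error reporting matches direct RMSE computation", {
  set.seed(46)
  obs <- runif(80, 0, 400)
  pred <- obs + rnorm(80, 0, 30)
  out <- anc_error_summary(obs, pred, split = 150)
  sel <- pred < 150
  expect_equal(out$rmse[out$stratum == "pred < 150"],
               sqrt(mean((obs[sel] - pred[sel])^2)))
  expect_equal(out$rmse[out$stratum == "full range"],
               sqrt(mean((obs - pred)^2)))
})
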