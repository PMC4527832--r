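test_that("the coupling slope recovers exact linear relations", {
  d <- tibble::tibble(mdat_c = 20:29, mdst_c = 0.5 * (20:29) + 3)
  expect_equal(estimate_beta(d)$beta, 0.5, tolerance = 1e-12)
  flat <- tibble::tibble(mdat_c = 20:29, mdst_c = rep(14, 10))
  expect_equal(estimate_beta(flat)$beta, 0, tolerance = 1e-12)
})

test_that("the slope equals the covariance/variance closed form", {
  set.seed(12)
  d <- tibble::tibble(mdat_c = rnorm(10, 25, 3))
  d$mdst_c <- 0.4 * d$mdat_c + rnorm(10)
  expect_equal(estimate_beta(d)$beta,
               cov(d$mdat_c, d$mdst_c) / var(d$mdat_c),
               tolerance = 1e-10)
})

test_that("constant air temperature makes the slope undefined", {
  d <- tibble::tibble(mdat_c = rep(25, 10), mdst_c = rnorm(10))
  expect_error(estimate_beta(d), "distinct MDAT")
})

test_that("observed sensitivity classification is boundary inclusive", {
  expect_equal(classify_sensitivity(c(0.275, 0.274999, 0.96, 0.02)),
               c("high", "low", "high", "low"))
  expect_error(classify_sensitivity(NaN), "finite")
})

test_that("a balanced symmetric design gives a zero logistic intercept", {
  d <- tibble::tibble(x = c(-1, -1, 1, 1), lab = c(0, 1, 0, 1))
  spec <- fit_logistic(d, "lab", "x")
  expect_equal(spec$intercept, 0, tolerance = 1e-6)
  expect_equal(unname(spec$coefficients["x"]), 0, tolerance = 1e-6)
})

test_that("predicted probabilities lie strictly in (0, 1)", {
  set.seed(14)
  d <- tibble::tibble(x = rnorm(200))
  d$lab <- as.integer(runif(200) < plogis(0.5 + 1.5 * d$x))
  spec <- fit_logistic(d, "lab", "x")
  p <- predict(spec, tibble::tibble(x = c(-8, rnorm(50), 8)))
  expect_true(all(p > 0 & p < 1))
})

test_that("complete separation is flagged but still reported", {
  d <- tibble::tibble(x = c(-(5:1), 1:5), lab = rep(c(0, 1), each = 5))
  expect_warning(spec <- fit_logistic(d, "lab", "x"), "separation")
  expect_true(spec$separation)
  expect_true(is.finite(spec$intercept))
})

test_that("predicted classification is inclusive at the probability cutoff", {
  spec <- logistic_spec(c(x = 1), intercept = 0, cutoff = 0.5)
  d <- tibble::tibble(reach_id = 1:3, x = c(0, -30, 30))
  out <- classify_sensitivity_predicted(d, spec)
  expect_equal(out$p_high[1], 0.5)
  expect_equal(out$sensitivity_class, c("high", "low", "high"))
})

test_that("the orientation flag flips the scored class coherently", {
  d <- tibble::tibble(reach_id = 1:5, x = c(-2, -1, 0, 1, 2))
  hi <- logistic_spec(c(x = 1.3), intercept = 0.2, event = "high")
  lo <- logistic_spec(c(x = -1.3), intercept = -0.2, event = "low")
  expect_equal(predict(hi, d), predict(lo, d), tolerance = 1e-12)
})

test_that("confusion summary matches brute-force counting", {
  set.seed(15)
  truth <- sample(c("high", "low"), 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.8, truth,
                 ifelse(truth == "high", "low", "high"))
  cm <- confusion_summary(truth, pred)
  tab <- table(truth, pred)
  expect_equal(cm$n_correct[cm$class == "high"], tab["high", "high"])
  expect_equal(cm$n_correct[cm$class == "low"], tab["low", "low"])
  expect_equal(cm$pct_correct[cm$class == "overall"],
               100 * sum(diag(tab)) / sum(tab))
  expect_error(confusion_summary(truth, pred[-1]), "equal length")
})

test_that("the slope model refuses low-sensitivity sites and recovers exact fits", {
  set.seed(16)
  d <- tibble::tibble(TWI = runif(30, 5, 15), BFI = runif(30, 30, 80))
  d$beta <- 0.3 + 0.02 * d$TWI - 0.001 * d$BFI  # all above threshold
  spec <- fit_beta_model(d, c("TWI", "BFI"))
  expect_equal(spec$r2, 1)
  expect_equal(unname(spec$coefficients["TWI"]), 0.02, tolerance = 1e-10)
  d_bad <- d
  d_bad$beta[1] <- 0.1
  expect_error(fit_beta_model(d_bad, c("TWI", "BFI")), "low-sensitivity")
})

test_that("published slope-model coefficients reproduce the TWI contrast", {
  spec <- linear_spec(regional_beta_coefs())
  base <- tibble::tibble(BFI = 50, WSAREA = 10, LITHSIL = 20, TWI = 8,
                         LITHCAR = 5)
  bumped <- dplyr::mutate(base, TWI = TWI + 1)
  expect_equal(predict(spec, bumped) - predict(spec, base), 0.0721,
               tolerance = 1e-12)
})

test_that("future projection warms only high-sensitivity reaches, linearly in delta", {
  set.seed(17)
  n <- 100
  d <- tibble::tibble(
    jmmst_c = runif(n, 12, 24),
    sensitivity_class = sample(c("high", "low"), n, replace = TRUE),
    beta_predicted = runif(n, -0.1, 0.9)
  )
  p2 <- project_future(d, 2)
  p4 <- project_future(d, 4)
  expect_true(all(p2$jmmst_future_c >= d$jmmst_c))          # monotone
  expect_equal(p4$jmmst_future_c - d$jmmst_c,
               2 * (p2$jmmst_future_c - d$jmmst_c), tolerance = 1e-12)
  low <- d$sensitivity_class == "low"
  expect_equal(p4$jmmst_future_c[low], d$jmmst_c[low])      # no warming
  # negative predicted slopes are floored at zero, never cooling
  neg <- d$beta_predicted < 0 & !low
  expect_equal(p4$jmmst_future_c[neg], d$jmmst_c[neg])
  expect_error(project_future(d, -1), "nonnegative")
})

test_that("end-to-end slope recovery error shrinks with series noise", {
  errs <- vapply(c(1.5, 0.5, 0.05), function(noise) {
    cfg <- generator_config(seed = 19, n_headwaters = 60, n_sites = 40,
                            noise_sd_stream_temp_C = noise)
    net <- generate_network(cfg)
    d <- generate_daily_series(net, cfg)
    est <- estimate_site_betas(d$series)
    mean(abs(est$beta - d$sites$beta_true))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
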