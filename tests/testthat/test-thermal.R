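test_that("noiseless data are fitted exactly", {
  d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  spec <- fit_ols(d, "y", "x")
  expect_equal(spec$intercept, 2)
  expect_equal(unname(spec$coefficients["x"]), 3)
  expect_equal(spec$r2, 1)
  expect_equal(spec$rmse, 0, tolerance = 1e-8)
})

test_that("estimates equal the closed-form normal-equations solution", {
  set.seed(4)
  d <- tibble::tibble(x = c(0.3, 1.1, 2.2, 3.5, 4.1))
  d$y <- c(1.2, 0.7, 2.9, 3.1, 5.0)
  spec <- fit_ols(d, "y", "x")
  xm <- cbind(1, d$x)
  beta_hat <- solve(t(xm) %*% xm, t(xm) %*% d$y)  # independent oracle
  expect_equal(spec$intercept, beta_hat[1, 1], tolerance = 1e-10)
  expect_equal(unname(spec$coefficients["x"]), beta_hat[2, 1],
               tolerance = 1e-10)
})

test_that("fit diagnostics satisfy the least-squares identities", {
  set.seed(5)
  d <- tibble::tibble(a = rnorm(60), b = rnorm(60))
  d$y <- 1 + 0.5 * d$a - 0.8 * d$b + rnorm(60)
  spec <- fit_ols(d, "y", c("a", "b"))
  res <- d$y - predict(spec, d)
  expect_lt(abs(mean(res)), 1e-9)
  expect_equal(spec$rmse, sqrt(mean(res^2)))
  expect_true(all(spec$vif >= 1))
})

test_that("rank-deficient designs fail naming the collinear term", {
  d <- tibble::tibble(a = rnorm(20))
  d$b <- 2 * d$a
  d$y <- d$a + rnorm(20)
  expect_error(fit_ols(d, "y", c("a", "b")), "collinear.*b")
})

test_that("prediction is an affine elementwise dot product", {
  set.seed(6)
  coefs <- c(JMMAT = 0.9, WSAREA = 0.02, BFI = -0.1)
  spec <- linear_spec(coefs, intercept = 3)
  newdata <- tibble::tibble(JMMAT = rnorm(100, 25), WSAREA = runif(100, 1, 50),
                            BFI = runif(100, 30, 80))
  pred <- predict(spec, newdata)
  manual <- vapply(seq_len(100), function(i) {
    3 + sum(coefs * unlist(newdata[i, names(coefs)]))
  }, numeric(1))
  expect_equal(pred, manual, tolerance = 1e-12)
  # affine: difference depends only on the covariate difference
  shift <- dplyr::mutate(newdata, JMMAT = JMMAT + 1)
  expect_equal(predict(spec, shift) - pred, rep(0.9, 100), tolerance = 1e-12)
  expect_error(predict(spec, newdata[, 1:2]), "missing model terms.*BFI")
})

test_that("zero coefficients predict the intercept everywhere", {
  spec <- linear_spec(c(JMMAT = 0), intercept = 7)
  expect_equal(predict(spec, tibble::tibble(JMMAT = rnorm(5))), rep(7, 5))
})

test_that("exhaustive subset selection matches brute-force enumeration", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 80
    d <- tibble::as_tibble(setNames(
      as.data.frame(matrix(rnorm(n * 5), n)), paste0("v", 1:5)
    ))
    d$y <- 1 + 1.2 * d$v1 - 0.9 * d$v3 + rnorm(n)
    spec <- select_model(d, "y", paste0("v", 1:5))
    oracle <- brute_force_select(d, "y", paste0("v", 1:5))
    expect_equal(sort(names(spec$coefficients)), oracle$terms)
    expect_equal(spec$aic, oracle$aic, tolerance = 1e-8)
    expect_identical(spec$search, "exhaustive")
  }
})

test_that("a strong true predictor among noise terms is always selected", {
  set.seed(22)
  n <- 200
  d <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 5), n)), paste0("v", 1:5)
  ))
  d$y <- 2 + 3 * d$v2 + rnorm(n)
  spec <- select_model(d, "y", paste0("v", 1:5))
  expect_true("v2" %in% names(spec$coefficients))
  # every term in the winner is significant
  expect_true(all(spec$p_values < 0.05))
})

test_that("all-noise candidates fall back to the intercept-only model", {
  set.seed(100)  # a seed where no noise term clears the significance bar
  n <- 150
  d <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 4), n)), paste0("v", 1:4)
  ))
  d$y <- rnorm(n)
  expect_warning(spec <- select_model(d, "y", paste0("v", 1:4)),
                 "intercept-only")
  expect_length(spec$coefficients, 0)
  expect_equal(predict(spec, d), rep(spec$intercept, n))
})

test_that("the forward search engages above the exhaustive limit and is flagged", {
  set.seed(23)
  n <- 120
  d <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 6), n)), paste0("v", 1:6)
  ))
  d$y <- 1 + 2 * d$v1 + 1.5 * d$v4 + rnorm(n)
  spec <- select_model(d, "y", paste0("v", 1:6), exhaustive_limit = 3)
  expect_identical(spec$search, "forward")
  expect_true(all(c("v1", "v4") %in% names(spec$coefficients)))
})
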