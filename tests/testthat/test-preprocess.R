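test_that("Box-Cox closed forms and round trip hold", {
  tr1 <- structure(list(lambda = 1, shift = 0), class = "leafq_boxcox")
  expect_equal(boxcox_apply(c(2, 5), tr1), c(1, 4))
  tr0 <- structure(list(lambda = 0, shift = 0), class = "leafq_boxcox")
  expect_equal(boxcox_apply(exp(1), tr0), 1)
  set.seed(1)
  v <- rlnorm(50)
  tr <- boxcox_fit(v)
  expect_equal(tr$shift, 0) # strictly positive input
  expect_equal(boxcox_invert(boxcox_apply(v, tr), tr), v, tolerance = 1e-9)
  vneg <- v - 2
  trn <- boxcox_fit(vneg)
  expect_true(min(vneg) + trn$shift > 0)
  expect_equal(boxcox_invert(boxcox_apply(vneg, trn), trn), vneg,
               tolerance = 1e-9)
  expect_error(boxcox_fit(rep(3, 10)), "degenerate")
  expect_error(boxcox_apply(c(-5, 1), tr0), "domain")
})

test_that("Box-Cox lambda is near 0 for log-normal data and reduces skewness", {
  set.seed(42)
  lambdas <- replicate(5, boxcox_fit(exp(rnorm(1000)))$lambda)
  expect_true(all(lambdas > -0.3 & lambdas < 0.3))
  # strongly right-skewed data become nearly symmetric
  set.seed(43)
  v <- rlnorm(1000)
  tr <- boxcox_fit(v)
  expect_lt(abs(skewness(boxcox_apply(v, tr))),
            0.05 * abs(skewness(v)))
  # already-symmetric data: skewness does not increase on average (the MLE
  # targets normality, so individual draws may move either way slightly)
  deltas <- vapply(1:20, function(s) {
    set.seed(s)
    v <- rnorm(500)
    tr <- boxcox_fit(v)
    abs(skewness(boxcox_apply(v, tr))) - abs(skewness(v))
  }, numeric(1))
  expect_lte(mean(deltas), 0.005)
})

test_that("profile-likelihood lambda agrees with the MASS grid oracle", {
  skip_if_not_installed("MASS")
  set.seed(9)
  for (v in list(rlnorm(400), rgamma(400, shape = 2), runif(400, 1, 5))) {
    ours <- boxcox_fit(v)$lambda
    bc <- MASS::boxcox(v ~ 1, lambda = seq(-5, 5, 0.01), plotit = FALSE)
    oracle <- bc$x[which.max(bc$y)]
    expect_equal(ours, oracle, tolerance = 0.02)
  }
})

test_that("z-score transform stores sample statistics and standardizes", {
  set.seed(2)
  prices <- rnorm(200, 1579996.5, 452320.3)
  res <- zscore_fit_apply(prices)
  expect_equal(res$transform$mean, mean(prices))
  expect_equal(res$transform$sd, sd(prices))
  expect_equal(mean(res$scaled), 0, tolerance = 1e-9)
  expect_equal(sd(res$scaled), 1, tolerance = 1e-9)
  # two-point case under the sample-sd (n - 1) convention
  expect_equal(zscore_fit_apply(c(0, 2))$scaled, c(-1, 1) / sqrt(2))
  z <- zscore_fit_apply(res$scaled)
  expect_equal(z$transform$mean, 0, tolerance = 1e-9)
  expect_equal(z$transform$sd, 1, tolerance = 1e-9)
  expect_equal(zscore_invert(res$scaled, res$transform), prices)
  expect_error(zscore_fit(rep(1, 5)), "zero variance")
})

test_that("range scaler maps endpoints, round-trips, and clamps with warning", {
  sc <- range_fit(c(0, 5, 10), -1, 1)
  expect_equal(range_apply(c(0, 5, 10), sc), c(-1, 0, 1))
  set.seed(3)
  v <- runif(50, 0, 10)
  expect_equal(range_invert(range_apply(v, sc), sc), v, tolerance = 1e-12)
  expect_warning(out <- range_apply(12, sc), "clamped")
  expect_equal(out, 1)
  expect_silent(range_apply(12, sc, warn = FALSE))
  expect_error(range_fit(rep(2, 4)), "degenerate")
  expect_error(range_fit(1:3, lo = 1, hi = 0), "hi")
})

test_that("PCA screen flags at roughly the nominal rate on clean normal data", {
  set.seed(4)
  rates <- replicate(20, {
    X <- matrix(rnorm(400 * 7), 400, 7)
    mean(pca_outlier_screen(X, alpha = 0.01))
  })
  expect_gt(mean(rates), 0.004)
  expect_lt(mean(rates), 0.02)
})

test_that("PCA screen catches a grossly displaced row but not clean leaf data", {
  set.seed(5)
  X <- matrix(rnorm(300 * 7), 300, 7)
  X[17, ] <- X[17, ] + 10
  flags <- pca_outlier_screen(X, alpha = 0.01)
  expect_true(flags[17])
  d <- generate_tobacco_like(generator_config(seed = 1))
  expect_equal(sum(pca_outlier_screen(predictor_matrix(d))), 0)
})

test_that("transforms serialize to JSON and re-apply bit-identically", {
  set.seed(6)
  v <- rlnorm(100)
  for (tr in list(boxcox_fit(v), zscore_fit(v), range_fit(v))) {
    path <- tempfile(fileext = ".json")
    write_transform_json(tr, path)
    back <- read_transform_json(path)
    expect_identical(class(back), class(tr))
    apply_fun <- switch(class(tr)[1],
                        leafq_boxcox = boxcox_apply,
                        leafq_zscore = zscore_apply,
                        leafq_range_scaler = range_apply)
    expect_identical(apply_fun(v, back), apply_fun(v, tr))
  }
})
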