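test_that("least squares recovers noiseless coefficients exactly", {
  gl <- generate_linear(c(-1, 2, 0.5, 0, 1, -3, 0.1), intercept = -2,
                        n_samples = 80, noise_sd = 0, seed = 1)
  for (fit in list(fit_mlr(gl$X, gl$y), fit_olsr(gl$X, gl$y))) {
    expect_equal(unname(fit$coefficients), c(-1, 2, 0.5, 0, 1, -3, 0.1),
                 tolerance = 1e-8)
    expect_equal(fit$intercept, -2, tolerance = 1e-8)
  }
  g0 <- generate_linear(rep(0, 7), intercept = 1, n_samples = 60,
                        noise_sd = 0.3, seed = 2)
  fit0 <- fit_mlr(g0$X, g0$y)
  expect_true(all(abs(fit0$coefficients) < 0.3))
})

test_that("rank-deficient designs fall back to a ridge jitter with warning", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 3] <- X[, 1] # exact collinearity
  y <- rnorm(60)
  expect_warning(fit <- fit_mlr(X, y), "rank-deficient")
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("full-component PCR and PLSR reproduce the least-squares fit", {
  gl <- generate_linear(c(1, -1, 2, 0, 0.3, -0.7, 1.2), 0.5, 120, 0.4,
                        seed = 4)
  base <- predict(fit_mlr(gl$X, gl$y), gl$X)
  expect_equal(predict(fit_pcr(gl$X, gl$y, 7), gl$X), base, tolerance = 1e-8)
  expect_equal(predict(fit_plsr(gl$X, gl$y, 7), gl$X), base, tolerance = 1e-6)
})

test_that("stepwise keeps a strong lone signal and drops pure noise", {
  supports <- lapply(1:100, function(s) {
    gl <- generate_linear(c(-1, 0, 0, 0, 0, 0, 0), 0, 200, 0.1, seed = s)
    fit_stepwise(gl$X, gl$y)$meta$variables
  })
  # the signal column is always found
  expect_true(all(vapply(supports, function(v) "bms" %in% v, logical(1))))
  # exact-support rate matches the procedure's family-wise false-entry rate:
  # each of the 6 noise columns enters with probability ~alpha_enter, so
  # P(only the signal) ~ 0.95^6 = 0.735; assert within a 3-sigma band
  exact <- mean(vapply(supports, identical, logical(1), "bms"))
  expect_gte(exact, 0.95^6 - 3 * sqrt(0.735 * 0.265 / 100))
  empty <- vapply(1:50, function(s) {
    gl <- generate_linear(rep(0, 7), 0, 100, 1, seed = 1000 + s)
    length(fit_stepwise(gl$X, gl$y)$meta$variables) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
  strong <- generate_linear(c(2, -2, 1.5, 1, -1, 2.5, -1.5), 0, 300, 0.1,
                            seed = 5)
  expect_setequal(fit_stepwise(strong$X, strong$y)$meta$variables,
                  colnames(strong$X))
  expect_error(fit_stepwise(strong$X, strong$y, alpha_enter = 0.2,
                            alpha_remove = 0.1), "alpha_enter")
})

test_that("one PCR component suffices when the signal lies in PC1", {
  set.seed(6)
  n <- 200
  f <- rnorm(n)
  X <- matrix(rep(f, 7), n, 7) + matrix(rnorm(n * 7, sd = 0.05), n, 7)
  colnames(X) <- paste0("x", 1:7)
  y <- 2 * f + rnorm(n, sd = 0.1)
  r2_1 <- r_squared(y, predict(fit_pcr(X, y, 1), X))
  r2_full <- r_squared(y, predict(fit_pcr(X, y, 7), X))
  expect_gt(r2_1, 0.95 * r2_full)
  # auto selection is no worse than the full least-squares fit on clean data
  gl <- generate_linear(c(1, 2, 3, 0, 0, 0, 0), 0, 100, 0, seed = 7)
  auto <- fit_pcr(gl$X, gl$y, "auto")
  expect_lte(rmse(gl$y, predict(auto, gl$X)),
             rmse(gl$y, predict(fit_mlr(gl$X, gl$y), gl$X)) + 1e-6)
})

test_that("PLS1 extracts the covariance-maximizing direction first", {
  # column-centered orthonormal design, y = first column: the first PLS
  # weight vector w1 ~ X'y is exactly e1, so one component fits perfectly
  set.seed(8)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 7), 100, 7))))[, 2:8]
  colnames(Q) <- paste0("x", 1:7)
  y <- Q[, 1]
  fit1 <- fit_plsr(Q, y, 1)
  expect_gt(r_squared(y, predict(fit1, Q)), 1 - 1e-8)
  # single-latent-factor data: one component captures the achievable fit
  f <- rnorm(150)
  X <- outer(f, seq(0.5, 2, length.out = 7)) +
    matrix(rnorm(150 * 7, sd = 0.05), 150, 7)
  colnames(X) <- paste0("x", 1:7)
  yy <- 3 * f + rnorm(150, sd = 0.1)
  r2_one <- r_squared(yy, predict(fit_plsr(X, yy, 1), X))
  r2_all <- r_squared(yy, predict(fit_plsr(X, yy, 7), X))
  expect_gt(r2_one, 0.99 * r2_all)
})

test_that("NIPALS PLS1 matches the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  gl <- generate_linear(c(1, -2, 0.5, 0, 3, -1, 0.2), 2, 90, 0.5, seed = 9)
  for (k in c(2, 4)) {
    ours <- predict(fit_plsr(gl$X, gl$y, k), gl$X)
    mo <- mixOmics::pls(gl$X, gl$y, ncomp = k, mode = "regression",
                        scale = TRUE)
    theirs <- drop(predict(mo, gl$X)$predict[, 1, k])
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  }
})

test_that("prediction matches by-hand arithmetic and validates columns", {
  m <- structure(list(method = "MLR", coefficients = c(a = 2, b = -1),
                      intercept = 0.5,
                      meta = list(variables = c("a", "b"), var_idx = 1:2,
                                  all_variables = c("a", "b"))),
                 class = "leafq_lm")
  X <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, X), c(2 * 1 - 1 * 3 + 0.5, 2 * 2 - 1 * 4 + 0.5))
  expect_error(predict(m, matrix(1:4, 2, 2,
                                 dimnames = list(NULL, c("a", "z")))),
               "missing retained")
  empty <- structure(list(method = "SR", coefficients = numeric(0),
                          intercept = 3,
                          meta = list(variables = character(0))),
                     class = "leafq_lm")
  expect_equal(predict(empty, X), c(3, 3))
})
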