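test_that("metrics match hand arithmetic and handle edge cases", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1.1, 1.9, 3.2)), 0.97)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2) # constant offset
  expect_equal(rmse(c(0, 0), c(0.3, -0.4)), sqrt((0.09 + 0.16) / 2))
  expect_equal(mape(2, 1), 50)
  expect_equal(mape(c(1, -2), c(1.1, -1.8)), 10)
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "constant")
  expect_error(mape(c(1, 0), c(1, 1)), "zero")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("metrics agree with brute-force recomputation", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    ya <- rnorm(n) + 2 # keep away from zero for MAPE
    ye <- ya + rnorm(n, sd = 0.5)
    sse <- 0
    sst <- 0
    sae <- 0
    for (j in seq_len(n)) {
      sse <- sse + (ye[j] - ya[j])^2
      sst <- sst + (ya[j] - mean(ya))^2
      sae <- sae + abs((ya[j] - ye[j]) / ya[j])
    }
    expect_equal(r_squared(ya, ye), 1 - sse / sst, tolerance = 1e-12)
    expect_equal(rmse(ya, ye), sqrt(sse / n), tolerance = 1e-12)
    expect_equal(mape(ya, ye), sae / n * 100, tolerance = 1e-12)
  }
})

test_that("fold plans are balanced partitions, reproducible from seed", {
  plan <- make_fold_plan(100, k = 5, repeats = 10, seed = 1)
  expect_equal(dim(plan$assignments), c(100, 10))
  for (r in 1:10) {
    expect_equal(as.vector(table(plan$assignments[, r])), rep(20, 5))
  }
  expect_gt(length(unique(apply(plan$assignments, 2, paste, collapse = ""))),
            1)
  expect_identical(plan, make_fold_plan(100, 5, 10, seed = 1))
  # uneven division: fold sizes differ by at most one
  p2 <- make_fold_plan(23, k = 5, repeats = 2, seed = 2)
  expect_lte(diff(range(table(p2$assignments[, 1]))), 1)
  expect_error(make_fold_plan(3, k = 5), "at least k")
})

test_that("a perfect model scores R2 = 1 and RMSE = 0 in cross-validation", {
  gl <- generate_linear(c(1, -1, 2, 0.5, 0, 0, 0), 3, 100, 0, seed = 3)
  plan <- make_fold_plan(100, 5, 2, seed = 4)
  res <- cross_validate(spec_baseline("mlr"), gl$X, gl$y, plan)
  expect_gt(res$testing$r2, 1 - 1e-10)
  expect_lt(res$testing$rmse, 1e-7)
  expect_gt(res$training$r2, 1 - 1e-10)
})

test_that("an out-of-fold mean predictor has non-positive testing R2", {
  mean_spec <- list(name = "MEAN",
                    fit = function(X, y) mean(y),
                    predict = function(model, X) rep(model, nrow(X)))
  set.seed(5)
  r2s <- replicate(10, {
    X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(60) + 5
    plan <- make_fold_plan(60, 5, 1, seed = sample.int(1000, 1))
    cross_validate(mean_spec, X, y, plan)$testing$r2
  })
  expect_lt(mean(r2s), 0)
})

test_that("cross-validation is bit-reproducible for deterministic models", {
  gl <- generate_linear(c(1, 0, 0, 0, 2, 0, 0), 0, 80, 0.5, seed = 6)
  plan <- make_fold_plan(80, 5, 2, seed = 7)
  r1 <- cross_validate(spec_baseline("plsr", n_components = 3), gl$X, gl$y,
                       plan, preprocess = NULL)
  r2 <- cross_validate(spec_baseline("plsr", n_components = 3), gl$X, gl$y,
                       plan, preprocess = NULL)
  expect_identical(r1, r2)
})

test_that("fold preprocessing never uses test rows (leakage audit)", {
  set.seed(8)
  X <- matrix(rlnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -1, 0.5)) + rnorm(90, sd = 0.2)
  plan <- make_fold_plan(90, 3, 1, seed = 9)
  res <- cross_validate(spec_baseline("mlr"), X, y, plan,
                        preprocess = list(boxcox = TRUE))
  # corrupt the rows of one test fold: training metrics of that cell must
  # be unchanged because no transform or fit may depend on test rows
  fold1 <- plan$assignments[, 1] == 1
  X2 <- X
  X2[fold1, ] <- X2[fold1, ] * 100
  res2 <- cross_validate(spec_baseline("mlr"), X2, y, plan,
                         preprocess = list(boxcox = TRUE))
  tr1 <- res$folds[res$folds$fold == 1 & res$folds$subset == "training", ]
  tr2 <- res2$folds[res2$folds$fold == 1 & res2$folds$subset == "training", ]
  expect_identical(tr1, tr2)
})

test_that("near-zero actual responses are excluded from MAPE with a count", {
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(0, rnorm(39) + 3) # one exactly-zero actual
  plan <- make_fold_plan(40, 4, 1, seed = 10)
  res <- cross_validate(spec_baseline("mlr"), X, y, plan)
  # the zero row is in 3 training portions and 1 test portion across folds
  expect_equal(sum(res$folds$mape_excluded), 4)
  expect_true(all(is.finite(res$folds$mape)))
})

test_that("metrics on the original scale survive the internal range scaling", {
  td <- generate_teacher_mlp(4, 3, 80, noise_sd = 0.05, seed = 11)
  y_big <- td$y * 1000 + 5000 # far from the network output scale
  cfg <- ga_config(population_size = 20, generations = 30, seed = 12,
                   local_refinement = TRUE)
  model <- fit_mlp_ga(td$X, y_big, n_hidden = 3, config = cfg)
  pred <- predict(model, td$X)
  model_z <- fit_mlp_ga(td$X, td$y, n_hidden = 3, config = cfg)
  pred_z <- predict(model_z, td$X)
  # same fit up to the affine response map
  expect_equal((pred - 5000) / 1000, pred_z, tolerance = 1e-9)
  expect_equal(r_squared(y_big, pred), r_squared(td$y, pred_z),
               tolerance = 1e-9)
})
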