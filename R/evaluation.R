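# Performance metrics and the repeated k-fold cross-validation protocol.

#' Coefficient of determination
#'
#' `1 - sum((y_est - y_act)^2) / sum((y_act - mean(y_act))^2)`.  Can be
#' negative for models worse than the mean predictor.
#'
#' @param y_act Actual values (length >= 2, not constant).
#' @param y_est Predicted values, same length.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y_act, y_est) {
  check_paired(y_act, y_est, min_len = 2L)
  ss_tot <- sum((y_act - mean(y_act))^2)
  if (ss_tot == 0) {
    stop("degenerate input: 'y_act' is constant, R-squared undefined",
         call. = FALSE)
  }
  1 - sum((y_est - y_act)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return Nonnegative scalar RMSE.
#' @export
rmse <- function(y_act, y_est) {
  check_paired(y_act, y_est, min_len = 1L)
  sqrt(mean((y_est - y_act)^2))
}

#' Mean absolute percentage error
#'
#' `mean(|(y_act - y_est) / y_act|) * 100`.  Undefined when any actual value
#' is (numerically) zero; on the z-score quality scale such rows can occur,
#' and [cross_validate()] excludes them with a logged count before calling
#' this function.
#'
#' @inheritParams r_squared
#' @return Nonnegative scalar, in percent.
#' @export
mape <- function(y_act, y_est) {
  check_paired(y_act, y_est, min_len = 1L)
  zero <- abs(y_act) < 1e-8
  if (any(zero)) {
    stop("domain error: 'y_act' is zero at row(s) ",
         paste(utils::head(which(zero), 5L), collapse = ", "),
         "; MAPE is undefined there", call. = FALSE)
  }
  mean(abs((y_act - y_est) / y_act)) * 100
}

check_paired <- function(y_act, y_est, min_len) {
  if (length(y_act) != length(y_est) || length(y_act) < min_len) {
    stop(sprintf("'y_act' and 'y_est' must have equal length >= %d", min_len),
         call. = FALSE)
  }
  if (anyNA(y_act) || anyNA(y_est)) {
    stop("metric inputs contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}

# MAPE with the near-zero-actual guard used inside cross-validation.
mape_guarded <- function(y_act, y_est) {
  keep <- abs(y_act) >= 1e-8
  n_excluded <- sum(!keep)
  value <- if (sum(keep) == 0) NA_real_ else mape(y_act[keep], y_est[keep])
  list(value = value, n_excluded = n_excluded)
}

#' Build a repeated k-fold plan
#'
#' For each repeat, rows are partitioned at random into `k` folds whose sizes
#' differ by at most one.  The study protocol is five folds with ten repeats.
#'
#' @param n Number of rows (>= k).
#' @param k Number of folds (default 5).
#' @param repeats Number of independent repartitions (default 10).
#' @param seed Integer RNG seed.
#' @return A `fold_plan` with an `n x repeats` assignment matrix of fold ids.
#' @export
make_fold_plan <- function(n, k = 5, repeats = 10, seed = 1) {
  n <- check_count(n, "n")
  k <- check_count(k, "k", min = 2)
  repeats <- check_count(repeats, "repeats")
  if (n < k) stop_config("n", sprintf("must be at least k = %d", k))
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  set.seed(seed)
  assignments <- vapply(seq_len(repeats),
                        function(r) sample(rep(seq_len(k), length.out = n)),
                        integer(n))
  structure(list(k = k, repeats = repeats, seed = seed,
                 assignments = matrix(assignments, nrow = n)),
            class = "fold_plan")
}

#' Model specification for cross-validation
#'
#' A model spec is a name plus a `fit(X, y)` / `predict(model, X)` closure
#' pair.  `spec_baseline` wraps the five linear baselines; `spec_mlp_ga`
#' wraps the GA-trained perceptron (which handles its own input/response
#' range scaling internally, so metrics come back on the original scale).
#'
#' @param method One of `"mlr", "sr", "olsr", "plsr", "pcr"`.
#' @param ... Extra arguments passed to the underlying fit function (e.g.
#'   `alpha_enter` for stepwise, `n_components` for PLSR/PCR).
#' @return A list with elements `name`, `fit`, `predict`.
#' @export
spec_baseline <- function(method = c("mlr", "sr", "olsr", "plsr", "pcr"), ...) {
  method <- match.arg(method)
  fit_fun <- switch(method,
                    mlr = fit_mlr, sr = fit_stepwise, olsr = fit_olsr,
                    plsr = fit_plsr, pcr = fit_pcr)
  args <- list(...)
  list(
    name = toupper(method),
    fit = function(X, y) do.call(fit_fun, c(list(X, y), args)),
    predict = function(model, X) predict(model, X)
  )
}

#' @rdname spec_baseline
#' @param n_hidden Hidden-neuron count of the perceptron.
#' @param config A [ga_config()].
#' @export
spec_mlp_ga <- function(n_hidden = 5, config = ga_config()) {
  list(
    name = "MLPNN-GA",
    fit = function(X, y) fit_mlp_ga(X, y, n_hidden = n_hidden, config = config),
    predict = function(model, X) predict(model, X)
  )
}

#' Repeated k-fold cross-validation
#'
#' For every repeat and fold, all preprocessing (and any model-internal
#' scaling) is fitted on the training portion only, the model is fitted, and
#' R-squared / RMSE / MAPE are computed on both portions on the original
#' response scale.  Reported training and testing records are means over all
#' repeat-by-fold cells; the per-cell table is returned for dispersion.
#' Rows whose actual response is numerically zero are excluded from MAPE
#' (the `mape_excluded` column counts them).
#'
#' @param model_spec A spec from [spec_baseline()] or [spec_mlp_ga()].
#' @param X Predictor matrix.
#' @param y Response vector (original scale).
#' @param fold_plan A [make_fold_plan()] plan for `nrow(X)` rows.
#' @param preprocess Optional list of switches; currently `boxcox = TRUE`
#'   Box-Cox-normalizes every predictor column (fit on the training fold).
#' @return A list with `training` and `testing` one-row metric data frames
#'   (columns `model, subset, r2, rmse, mape`) and a `folds` data frame of
#'   per-cell metrics.
#' @export
cross_validate <- function(model_spec, X, y, fold_plan, preprocess = NULL) {
  X <- check_matrix(X)
  stopifnot(inherits(fold_plan, "fold_plan"))
  if (nrow(fold_plan$assignments) != nrow(X) || length(y) != nrow(X)) {
    stop("fold plan, 'X' and 'y' disagree on the number of rows",
         call. = FALSE)
  }
  use_boxcox <- isTRUE(preprocess$boxcox)
  cells <- list()
  for (r in seq_len(fold_plan$repeats)) {
    assignment <- fold_plan$assignments[, r]
    for (fold in seq_len(fold_plan$k)) {
      test_idx <- which(assignment == fold)
      train_idx <- which(assignment != fold)
      X_tr <- X[train_idx, , drop = FALSE]
      X_te <- X[test_idx, , drop = FALSE]
      if (use_boxcox) {
        transforms <- apply(X_tr, 2, boxcox_fit, simplify = FALSE)
        for (j in seq_along(transforms)) {
          X_tr[, j] <- boxcox_apply(X_tr[, j], transforms[[j]])
          # clamp so the shifted test values stay in the transform's domain
          lo <- -transforms[[j]]$shift + 1e-12
          X_te[, j] <- boxcox_apply(pmax(X_te[, j], lo), transforms[[j]])
        }
      }
      model <- model_spec$fit(X_tr, y[train_idx])
      for (subset in c("training", "testing")) {
        idx <- if (subset == "training") train_idx else test_idx
        Xs <- if (subset == "training") X_tr else X_te
        pred <- model_spec$predict(model, Xs)
        mp <- mape_guarded(y[idx], pred)
        cells[[length(cells) + 1L]] <- data.frame(
          rep = r, fold = fold, subset = subset,
          r2 = r_squared(y[idx], pred), rmse = rmse(y[idx], pred),
          mape = mp$value, mape_excluded = mp$n_excluded
        )
      }
    }
  }
  folds <- do.call(rbind, cells)
  summarize <- function(subset) {
    sub <- folds[folds$subset == subset, , drop = FALSE]
    data.frame(model = model_spec$name, subset = subset,
               r2 = mean(sub$r2), rmse = mean(sub$rmse),
               mape = mean(sub$mape, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  list(training = summarize("training"), testing = summarize("testing"),
       folds = folds)
}
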