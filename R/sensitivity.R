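# Variable-importance analysis by ablation: the variable sensitivity error
# (VSE) is the model RMSE when one input is neutralized ("removed or
# unavailable"); the variable sensitivity ratio (VSR) divides VSE by the
# full-model RMSE; min-max rescaled VSRs rank the inputs on [0, 1].

#' Variable sensitivity error
#'
#' RMSE of a fitted model's predictions when one input column is neutralized.
#' Policies: `"mean"` (default) replaces the column by its training mean --
#' the common reading of an unavailable variable; `"permute"` shuffles it
#' (seeded); `"retrain"` refits without the column via `fit_fun`.
#'
#' @param model A fitted model accepted by `predict_fun`.
#' @param X_eval Evaluation predictor matrix (named columns).
#' @param y_eval Evaluation response.
#' @param variable Column name to neutralize.
#' @param neutralize Neutralization policy.
#' @param train_X Matrix supplying the imputation mean (defaults to
#'   `X_eval`).
#' @param predict_fun Prediction function `(model, X) -> vector`.
#' @param fit_fun Required for `"retrain"`: `(X, y) -> model`.
#' @param seed RNG seed of the `"permute"` policy.
#' @return Nonnegative RMSE under ablation.
#' @export
variable_sensitivity_error <- function(model, X_eval, y_eval, variable,
                                       neutralize = c("mean", "permute", "retrain"),
                                       train_X = NULL,
                                       predict_fun = stats::predict,
                                       fit_fun = NULL, seed = 1) {
  neutralize <- match.arg(neutralize)
  X_eval <- check_matrix(X_eval, "X_eval")
  if (is.null(colnames(X_eval)) || !variable %in% colnames(X_eval)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  train_X <- train_X %||% X_eval
  if (neutralize == "retrain") {
    if (is.null(fit_fun)) {
      stop("the 'retrain' policy requires 'fit_fun'", call. = FALSE)
    }
    keep <- setdiff(colnames(X_eval), variable)
    refit <- fit_fun(train_X[, keep, drop = FALSE], y_eval)
    return(rmse(y_eval, predict_fun(refit, X_eval[, keep, drop = FALSE])))
  }
  Xa <- X_eval
  if (neutralize == "mean") {
    Xa[, variable] <- mean(train_X[, variable])
  } else {
    set.seed(seed)
    Xa[, variable] <- sample(Xa[, variable])
  }
  rmse(y_eval, predict_fun(model, Xa))
}

#' Variable sensitivity ratio
#'
#' `vse / baseline_rmse`, where the baseline is the model RMSE with all
#' inputs available.  A ratio near 1 means the model barely uses the
#' variable; larger ratios mean larger importance.
#'
#' @param vse Nonnegative ablation RMSE.
#' @param baseline_rmse Positive full-model RMSE.
#' @return Nonnegative ratio.
#' @export
vsr <- function(vse, baseline_rmse) {
  vse <- check_number(vse, "vse", min = 0)
  if (!is.numeric(baseline_rmse) || length(baseline_rmse) != 1L ||
      !is.finite(baseline_rmse) || baseline_rmse <= 0) {
    stop(paste("degenerate model: baseline RMSE is zero (or invalid), so the",
               "VSE/baseline ratio is undefined; add a tiny epsilon to the",
               "baseline or rank variables by raw VSE instead"),
         call. = FALSE)
  }
  vse / baseline_rmse
}

#' Min-max rescaling of raw VSR values
#'
#' Maps the raw ratios onto \[0, 1\] by `(v - min) / (max - min)`, so the most
#' sensitive variable scores exactly 1 and the least sensitive exactly 0.
#' If all ratios are equal, every variable maps to 1 with a warning.
#'
#' @param vsr_raw Named numeric vector of raw ratios.
#' @return Named numeric vector in \[0, 1\].
#' @export
rescale_vsr <- function(vsr_raw) {
  if (length(vsr_raw) < 1L) stop("'vsr_raw' must be nonempty", call. = FALSE)
  rng <- range(vsr_raw)
  if (diff(rng) == 0) {
    warning("all raw VSR values are equal; every variable rescales to 1",
            call. = FALSE)
    return(stats::setNames(rep(1, length(vsr_raw)), names(vsr_raw)))
  }
  (vsr_raw - rng[1L]) / diff(rng)
}

#' Full sensitivity report
#'
#' Computes the baseline RMSE, the per-variable VSE, raw VSR, and min-max
#' rescaled VSR, and the importance ranking (descending rescaled VSR).  By
#' default the report is computed on all available rows, mirroring an
#' importance analysis run on the complete dataset after model selection.
#'
#' @inheritParams variable_sensitivity_error
#' @return A `sensitivity_report`: `baseline_rmse`, `table` (data frame with
#'   columns `variable, vse, vsr_raw, vsr_rescaled`, sorted by importance)
#'   and `ranking` (character vector).
#' @export
build_sensitivity_report <- function(model, X_eval, y_eval,
                                     train_X = NULL,
                                     neutralize = c("mean", "permute", "retrain"),
                                     predict_fun = stats::predict,
                                     fit_fun = NULL, seed = 1) {
  neutralize <- match.arg(neutralize)
  X_eval <- check_matrix(X_eval, "X_eval")
  if (is.null(colnames(X_eval))) {
    stop("'X_eval' must have column names", call. = FALSE)
  }
  baseline <- rmse(y_eval, predict_fun(model, X_eval))
  vars <- colnames(X_eval)
  vse_vals <- vapply(vars, function(v) {
    variable_sensitivity_error(model, X_eval, y_eval, v,
                               neutralize = neutralize, train_X = train_X,
                               predict_fun = predict_fun, fit_fun = fit_fun,
                               seed = seed)
  }, numeric(1))
  vsr_raw <- vapply(vse_vals, vsr, numeric(1), baseline_rmse = baseline)
  resc <- rescale_vsr(vsr_raw)
  ord <- order(resc, decreasing = TRUE)
  tab <- data.frame(variable = vars, vse = vse_vals, vsr_raw = vsr_raw,
                    vsr_rescaled = resc, row.names = NULL,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(baseline_rmse = baseline, table = tab,
                 ranking = tab$variable, neutralize = neutralize),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity report> baseline RMSE %.4g, policy '%s'\n",
              x$baseline_rmse, x$neutralize))
  print(x$table, digits = 4)
  invisible(x)
}
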