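# The five linear regression baselines benchmarked against the GA-trained
# perceptron: multiple linear regression (MLR), bidirectional p-value
# stepwise regression (SR), ordinary least squares regression (OLSR), PLS1
# partial least squares (PLSR, NIPALS), and principal component regression
# (PCR).  MLR and OLSR are the same estimator for a fixed design; both
# labels are kept so reports mirror the conventional five-family comparison.

new_leafq_lm <- function(method, coefficients, intercept, meta) {
  structure(list(method = method, coefficients = coefficients,
                 intercept = intercept, meta = meta),
            class = "leafq_lm")
}

resolve_columns <- function(X, p_train) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Multiple linear / ordinary least squares regression
#'
#' Least-squares fit of `y` on all columns of `X` with an intercept.  `fit_mlr`
#' and `fit_olsr` are the identical estimator (they differ only in the report
#' label); on a fixed design the two families coincide mathematically.  A
#' rank-deficient design triggers a warning and a small ridge jitter so a
#' unique solution is still returned.
#'
#' @param X Predictor matrix, `nrow(X) > ncol(X)`.
#' @param y Response vector.
#' @return A `leafq_lm` model.
#' @export
fit_mlr <- function(X, y) fit_ols_impl(X, y, "MLR")

#' @rdname fit_mlr
#' @export
fit_olsr <- function(X, y) fit_ols_impl(X, y, "OLSR")

fit_ols_impl <- function(X, y, method) {
  X <- resolve_columns(check_matrix(X))
  if (nrow(X) <= ncol(X)) stop("'X' must have more rows than columns",
                               call. = FALSE)
  Z <- cbind(`(Intercept)` = 1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    warning("rank-deficient design; applying a small ridge jitter",
            call. = FALSE)
    co <- drop(solve(crossprod(Z) + diag(1e-8, ncol(Z)), crossprod(Z, y)))
  } else {
    co <- qr.coef(qz, y)
  }
  new_leafq_lm(method, co[-1L], co[[1L]],
               list(variables = colnames(X), var_idx = seq_len(ncol(X)),
                    all_variables = colnames(X)))
}

#' Bidirectional stepwise regression
#'
#' Classical p-value stepwise selection: starting from the empty model, the
#' most significant candidate is added while its partial-F p-value is below
#' `alpha_enter`; after each addition, any retained term whose p-value
#' exceeds `alpha_remove` is dropped; the cycle repeats to a fixpoint.  The
#' procedure is deterministic given the data.
#'
#' @inheritParams fit_mlr
#' @param alpha_enter Entry threshold (default 0.05).
#' @param alpha_remove Removal threshold (default 0.10); must be >=
#'   `alpha_enter`.
#' @return A `leafq_lm` with the retained variables in `meta$variables`
#'   (possibly none: an intercept-only model).
#' @export
fit_stepwise <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10) {
  X <- resolve_columns(check_matrix(X))
  alpha_enter <- check_number(alpha_enter, "alpha_enter", 0, 1)
  alpha_remove <- check_number(alpha_remove, "alpha_remove", 0, 1)
  if (alpha_enter > alpha_remove) {
    stop_config("alpha_enter", "must not exceed alpha_remove")
  }
  vars <- colnames(X)
  d <- data.frame(.y = y, X, check.names = FALSE)
  current <- character(0)
  term_p <- function(active) {
    # marginal partial-F p-value of each active term (equals the t-test)
    fml <- stats::reformulate(sprintf("`%s`", active), response = ".y")
    fit <- stats::lm(fml, data = d)
    sm <- stats::summary.lm(fit)$coefficients
    stats::setNames(sm[-1L, 4L], active)
  }
  for (iter in seq_len(50L)) {
    changed <- FALSE
    candidates <- setdiff(vars, current)
    if (length(candidates)) {
      pvals <- vapply(candidates, function(v) term_p(c(current, v))[[v]],
                      numeric(1))
      if (min(pvals) < alpha_enter) {
        current <- c(current, candidates[which.min(pvals)])
        changed <- TRUE
      }
    }
    while (length(current)) {
      pvals <- term_p(current)
      if (max(pvals) > alpha_remove) {
        current <- setdiff(current, names(pvals)[which.max(pvals)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(current)) {
    fml <- stats::reformulate(sprintf("`%s`", current), response = ".y")
    co <- stats::coef(stats::lm(fml, data = d))
    names(co) <- c("(Intercept)", current)
    coefs <- co[current]
  } else {
    co <- c(`(Intercept)` = mean(y))
    coefs <- stats::setNames(numeric(0), character(0))
  }
  new_leafq_lm("SR", coefs, co[[1L]],
               list(variables = current, var_idx = match(current, vars),
                    all_variables = vars,
                    alpha_enter = alpha_enter, alpha_remove = alpha_remove))
}

# Mean inner-CV RMSE over folds for each candidate component count.
select_ncomp_cv <- function(X, y, fitter, max_comp,
                            cv = list(k = 5, repeats = 1, seed = 1)) {
  plan <- make_fold_plan(nrow(X), k = cv$k %||% 5, repeats = cv$repeats %||% 1,
                         seed = cv$seed %||% 1)
  score <- numeric(max_comp)
  for (k in seq_len(max_comp)) {
    errs <- c()
    for (r in seq_len(plan$repeats)) {
      for (fold in seq_len(plan$k)) {
        te <- plan$assignments[, r] == fold
        m <- fitter(X[!te, , drop = FALSE], y[!te], k)
        errs <- c(errs, rmse(y[te], predict(m, X[te, , drop = FALSE])))
      }
    }
    score[k] <- mean(errs)
  }
  which.min(score)
}

#' Principal component regression
#'
#' Regresses `y` on the leading principal-component scores of the
#' standardized predictors and back-transforms to coefficients on the
#' original scale.  With all components PCR reproduces the full
#' least-squares fit.
#'
#' @inheritParams fit_mlr
#' @param n_components Number of components (1..`ncol(X)`), or `"auto"` to
#'   select by inner cross-validated RMSE.
#' @param cv Inner-CV settings used when `n_components = "auto"`.
#' @return A `leafq_lm` with `meta$n_components`.
#' @export
fit_pcr <- function(X, y, n_components = "auto",
                    cv = list(k = 5, repeats = 1, seed = 1)) {
  X <- resolve_columns(check_matrix(X))
  p <- ncol(X)
  if (identical(n_components, "auto")) {
    n_components <- select_ncomp_cv(X, y, function(Xt, yt, k) {
      fit_pcr(Xt, yt, n_components = k)
    }, p, cv)
  }
  k <- check_count(n_components, "n_components")
  if (k > p) stop_config("n_components", sprintf("must be <= %d", p))
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("constant predictor column; cannot standardize",
                        call. = FALSE)
  Xs <- scale(X, center = mu, scale = s)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, scores), y)
  gamma <- fit$coefficients[-1L]
  beta_s <- drop(pc$rotation[, seq_len(k), drop = FALSE] %*% gamma)
  beta <- beta_s / s
  intercept <- fit$coefficients[[1L]] - sum(beta * mu)
  new_leafq_lm("PCR", stats::setNames(beta, colnames(X)), intercept,
               list(variables = colnames(X), var_idx = seq_len(p),
                    all_variables = colnames(X), n_components = k))
}

#' Partial least squares regression (PLS1, NIPALS)
#'
#' Iteratively extracts score/loading pairs maximizing covariance between
#' the standardized predictors and the deflated response, and accumulates
#' the regression coefficients over components.  With all components PLS1
#' reproduces the full least-squares fit.
#'
#' @inheritParams fit_pcr
#' @return A `leafq_lm` with `meta$n_components`.
#' @export
fit_plsr <- function(X, y, n_components = "auto",
                     cv = list(k = 5, repeats = 1, seed = 1)) {
  X <- resolve_columns(check_matrix(X))
  p <- ncol(X)
  if (identical(n_components, "auto")) {
    n_components <- select_ncomp_cv(X, y, function(Xt, yt, k) {
      fit_plsr(Xt, yt, n_components = k)
    }, p, cv)
  }
  A <- check_count(n_components, "n_components")
  if (A > p) stop_config("n_components", sprintf("must be <= %d", p))
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("constant predictor column; cannot standardize",
                        call. = FALSE)
  Xc <- scale(X, center = mu, scale = s)
  yc <- y - mean(y)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      warning(sprintf("response fully deflated after %d component(s)", a - 1L),
              call. = FALSE)
      break
    }
    w <- w / wn
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    W[, a] <- w
    P[, a] <- drop(crossprod(Xc, t_sc)) / tt
    q[a] <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, P[, a])
    yc <- yc - q[a] * t_sc
    a_eff <- a
  }
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  beta_s <- drop(W %*% solve(crossprod(P, W), q))
  beta <- beta_s / s
  intercept <- mean(y) - sum(beta * mu)
  new_leafq_lm("PLSR", stats::setNames(beta, colnames(X)), intercept,
               list(variables = colnames(X), var_idx = seq_len(p),
                    all_variables = colnames(X), n_components = a_eff))
}

#' Predict from a linear baseline model
#'
#' @param object A `leafq_lm`.
#' @param newdata Predictor matrix; retained columns are matched by name when
#'   `newdata` has column names, otherwise by training position.
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.leafq_lm <- function(object, newdata, ...) {
  newdata <- check_matrix(newdata, "newdata")
  vars <- object$meta$variables
  if (length(vars) == 0L) {
    return(rep(object$intercept, nrow(newdata)))
  }
  if (!is.null(colnames(newdata))) {
    missing_cols <- setdiff(vars, colnames(newdata))
    if (length(missing_cols)) {
      stop("'newdata' is missing retained column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    Xp <- newdata[, vars, drop = FALSE]
  } else {
    if (ncol(newdata) < max(object$meta$var_idx)) {
      stop("'newdata' has too few columns for this model", call. = FALSE)
    }
    Xp <- newdata[, object$meta$var_idx, drop = FALSE]
  }
  object$intercept + drop(Xp %*% object$coefficients)
}

#' @export
print.leafq_lm <- function(x, ...) {
  cat(sprintf("<%s model> %d retained predictor(s)\n", x$method,
              length(x$coefficients)))
  if (!is.null(x$meta$n_components)) {
    cat("components:", x$meta$n_components, "\n")
  }
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}
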