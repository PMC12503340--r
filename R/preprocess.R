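# Data transforms fitted on training folds and re-applied elsewhere: Box-Cox
# power normalization, z-scoring, linear range scaling, and a PCA-based
# outlier screen.

#' Fit a Box-Cox power transform
#'
#' Estimates the power parameter lambda by maximizing the Box-Cox profile
#' log-likelihood with Brent's method over lambda in \[-5, 5\].  If the data
#' are not strictly positive a shift is first added so that the minimum maps
#' to half a standard deviation above zero (a minimum at machine epsilon
#' would let the power transform explode on the low tail).
#'
#' @param values Numeric vector, length >= 3, not all equal.
#' @return An object of class `leafq_boxcox` with fields `lambda` and `shift`.
#' @seealso [boxcox_apply()], [boxcox_invert()]
#' @export
#' @examples
#' tr <- boxcox_fit(rlnorm(200))
#' z <- boxcox_apply(rlnorm(5), tr)
boxcox_fit <- function(values) {
  if (length(values) < 3L || anyNA(values)) {
    stop("'values' must be at least 3 non-missing numbers", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("degenerate input: all values equal; Box-Cox is undefined",
         call. = FALSE)
  }
  shift <- if (min(values) > 0) 0 else 0.5 * stats::sd(values) - min(values)
  v <- values + shift
  n <- length(v)
  slog <- sum(log(v))
  profile_ll <- function(lambda) {
    w <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
    s2 <- mean((w - mean(w))^2)
    -n / 2 * log(s2) + (lambda - 1) * slog
  }
  opt <- stats::optimize(profile_ll, interval = c(-5, 5), maximum = TRUE,
                         tol = 1e-6)
  structure(list(lambda = opt$maximum, shift = shift), class = "leafq_boxcox")
}

#' Apply or invert a Box-Cox transform
#'
#' `boxcox_apply` computes `((v + shift)^lambda - 1) / lambda` (or
#' `log(v + shift)` when lambda = 0); `boxcox_invert` is its exact inverse.
#'
#' @param values Numeric vector.
#' @param transform A `leafq_boxcox` object from [boxcox_fit()].
#' @return Transformed (or back-transformed) numeric vector.
#' @export
boxcox_apply <- function(values, transform) {
  stopifnot(inherits(transform, "leafq_boxcox"))
  v <- values + transform$shift
  if (any(v <= 0)) {
    stop("domain error: values are not strictly positive after shift",
         call. = FALSE)
  }
  if (abs(transform$lambda) < 1e-12) log(v) else (v^transform$lambda - 1) / transform$lambda
}

#' @rdname boxcox_apply
#' @export
boxcox_invert <- function(values, transform) {
  stopifnot(inherits(transform, "leafq_boxcox"))
  lam <- transform$lambda
  v <- if (abs(lam) < 1e-12) exp(values) else (values * lam + 1)^(1 / lam)
  v - transform$shift
}

#' Fit and apply a z-score transform
#'
#' Centers and scales to unit variance using the sample standard deviation
#' (n - 1 denominator).  The response variable of the study -- market price
#' per kg dry weight -- enters the models on this scale.
#'
#' @param values Numeric vector of length >= 2 with nonzero variance.
#' @return `zscore_fit` returns a `leafq_zscore` object (fields `mean`, `sd`);
#'   `zscore_fit_apply` returns `list(transform, scaled)`.
#' @export
zscore_fit <- function(values) {
  if (length(values) < 2L || anyNA(values)) {
    stop("'values' must be at least 2 non-missing numbers", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  structure(list(mean = mean(values), sd = s), class = "leafq_zscore")
}

#' @rdname zscore_fit
#' @export
zscore_fit_apply <- function(values) {
  tr <- zscore_fit(values)
  list(transform = tr, scaled = zscore_apply(values, tr))
}

#' @rdname zscore_fit
#' @param transform A `leafq_zscore` object.
#' @export
zscore_apply <- function(values, transform) {
  stopifnot(inherits(transform, "leafq_zscore"))
  (values - transform$mean) / transform$sd
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(values, transform) {
  stopifnot(inherits(transform, "leafq_zscore"))
  values * transform$sd + transform$mean
}

#' Linear scaling onto a fixed interval
#'
#' Maps the training minimum to `lo` and maximum to `hi`, linearly in
#' between.  Needed because the tansig output neuron can only produce values
#' in (-1, 1): the training pipeline scales the response to \[-0.9, 0.9\] and
#' the predictors to \[-1, 1\].  At inference time values outside the training
#' range are clamped (with a warning unless `warn = FALSE`).
#'
#' @param values Numeric training vector with at least two distinct values.
#' @param lo,hi Target interval endpoints, `hi > lo`.
#' @return `range_fit` returns a `leafq_range_scaler`; `range_apply` and
#'   `range_invert` return numeric vectors.
#' @export
#' @examples
#' sc <- range_fit(c(0, 5, 10), -1, 1)
#' range_apply(c(0, 5, 10), sc) # -1 0 1
range_fit <- function(values, lo = -1, hi = 1) {
  if (hi <= lo) stop_config("hi", "must exceed lo")
  mn <- min(values)
  mx <- max(values)
  if (mx == mn) {
    stop("degenerate input: constant vector cannot be range-scaled",
         call. = FALSE)
  }
  structure(list(min = mn, max = mx, lo = lo, hi = hi),
            class = "leafq_range_scaler")
}

#' @rdname range_fit
#' @param scaler A `leafq_range_scaler` object.
#' @param warn Warn when clamping out-of-range values.
#' @export
range_apply <- function(values, scaler, warn = TRUE) {
  stopifnot(inherits(scaler, "leafq_range_scaler"))
  out_of_range <- values < scaler$min | values > scaler$max
  if (any(out_of_range)) {
    if (warn) {
      warning(sprintf("%d value(s) outside the training range were clamped",
                      sum(out_of_range)), call. = FALSE)
    }
    values <- pmin(pmax(values, scaler$min), scaler$max)
  }
  scaler$lo + (values - scaler$min) / (scaler$max - scaler$min) *
    (scaler$hi - scaler$lo)
}

#' @rdname range_fit
#' @export
range_invert <- function(values, scaler) {
  stopifnot(inherits(scaler, "leafq_range_scaler"))
  scaler$min + (values - scaler$lo) / (scaler$hi - scaler$lo) *
    (scaler$max - scaler$min)
}

#' PCA outlier screen
#'
#' Flags multivariate outliers by Hotelling's T-squared on the leading
#' principal components of the standardized data.  Components are retained up
#' to >= 95% cumulative variance; a row is flagged when its T-squared exceeds
#' the `(1 - alpha)` quantile of the scaled F reference distribution
#' `k (n - 1) / (n - k) F(k, n - k)`.
#'
#' @param X Numeric matrix, `n > p`.
#' @param alpha Significance level of the screen (default 0.01).
#' @return Logical vector of length `nrow(X)`; `TRUE` marks a flagged row.
#'   The T-squared statistics and threshold are attached as attributes
#'   `"t2"` and `"threshold"`.
#' @export
pca_outlier_screen <- function(X, alpha = 0.01) {
  X <- check_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("'X' must have more rows than columns", call. = FALSE)
  check_number(alpha, "alpha", min = 1e-12, max = 0.5)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping constant column(s) before PCA screening", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  k <- which(cumsum(ev) / sum(ev) >= 0.95)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
  thr <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  flags <- t2 > thr
  attr(flags, "t2") <- t2
  attr(flags, "threshold") <- thr
  flags
}

#' Serialize a fitted transform to JSON
#'
#' @param transform A `leafq_boxcox`, `leafq_zscore` or `leafq_range_scaler`.
#' @param path File path.
#' @return `path`, invisibly; `read_transform_json` returns the transform.
#' @export
write_transform_json <- function(transform, path) {
  cls <- class(transform)[1L]
  if (!cls %in% c("leafq_boxcox", "leafq_zscore", "leafq_range_scaler")) {
    stop("unsupported transform class: ", cls, call. = FALSE)
  }
  jsonlite::write_json(c(list(class = cls), unclass(transform)), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  structure(lapply(obj, as.numeric), class = cls)
}
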