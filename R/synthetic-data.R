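# Synthetic data generators.  Field measurements of leaf quality are not
# publicly deposited, so the pipeline is exercised on generated data that
# reproduces the *statistical shape* of the study: 4 cultivars x 2 growing
# seasons, 100 plants per cultivar, 7 predictors with cultivar- and
# season-specific means inside plausible agronomic ranges, and a z-scored
# quality response dominated by a negative, saturating blue-mold-severity
# effect with smaller chemical-composition effects plus Gaussian noise.

leafq_predictors <- c("bms", "chl", "n", "s", "nt", "cl", "k")

# Plausible ranges (bms %, chl index, the rest % w/w)
leafq_ranges <- list(
  bms = c(0, 60), chl = c(25, 50), n = c(1, 4), s = c(0, 15),
  nt = c(0, 35), cl = c(0, 4), k = c(1, 4)
)

# Cultivar x season predictor means.  Anchored on the reported field
# contrasts (e.g. highest blue mold in Bergerac, highest chlorophyll and
# sugar in Bell, highest nicotine and potassium in Burly, lowest nicotine in
# Basma); values without a reported anchor are mid-range.
leafq_profile_means <- list(
  "1" = list( # first season
    Bergerac = c(bms = 22.8, chl = 38.7, n = 2.20, s = 5.5, nt = 20.0, cl = 2.50, k = 2.20),
    Bell     = c(bms = 4.5,  chl = 45.5, n = 2.10, s = 12.5, nt = 18.0, cl = 1.30, k = 2.40),
    Burly    = c(bms = 15.0, chl = 41.0, n = 2.74, s = 0.9, nt = 31.1, cl = 1.10, k = 3.26),
    Basma    = c(bms = 12.0, chl = 42.0, n = 2.30, s = 5.7, nt = 2.5,  cl = 1.40, k = 2.50)
  ),
  "2" = list( # second season
    Bergerac = c(bms = 35.5, chl = 33.5, n = 2.87, s = 7.0, nt = 24.8, cl = 2.71, k = 1.62),
    Bell     = c(bms = 9.1,  chl = 38.6, n = 1.61, s = 11.0, nt = 15.0, cl = 1.50, k = 2.20),
    Burly    = c(bms = 20.0, chl = 33.9, n = 2.20, s = 6.5, nt = 24.8, cl = 0.66, k = 2.84),
    Basma    = c(bms = 15.0, chl = 36.0, n = 2.30, s = 4.4, nt = 1.5,  cl = 1.20, k = 2.30)
  )
)

leafq_profile_sds <- c(bms = 5, chl = 2.5, n = 0.25, s = 1.2, nt = 2.5,
                       cl = 0.35, k = 0.25)

#' Configuration of the tobacco-like data generator
#'
#' @param n_per_cultivar Rows generated per cultivar (default 100, split
#'   evenly over the seasons); must be >= 10.
#' @param cultivars Character vector of cultivar labels.
#' @param seasons Character vector of season labels.
#' @param noise_sd Standard deviation of Gaussian noise added to the quality
#'   response, on the z-score scale.
#' @param bms_effect Signed weight of the blue-mold-severity driver on
#'   quality; negative by default (more disease, lower quality) and, at the
#'   defaults, strictly the largest effect in magnitude.
#' @param minor_effects Named numeric vector of smaller effects of the
#'   chemical predictors (names among `chl, n, s, nt, cl, k`), applied to the
#'   z-scored predictor columns.
#' @param nonlin_scale Mixing weight in \[0, 1\] of the saturating (tanh)
#'   component of the blue-mold driver; 0 makes the response generation
#'   purely affine.  The default 0.75 models a strongly saturating
#'   disease-damage response (quality loss levels off at high severity).
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_per_cultivar = 100,
                             cultivars = c("Bergerac", "Bell", "Burly", "Basma"),
                             seasons = c("2015", "2016"),
                             noise_sd = 0.3,
                             bms_effect = -1,
                             minor_effects = c(chl = 0.3, n = 0.2, s = 0.25,
                                               nt = -0.15, cl = -0.2, k = 0.15),
                             nonlin_scale = 0.75,
                             seed = 1) {
  n_per_cultivar <- check_count(n_per_cultivar, "n_per_cultivar", min = 10)
  if (length(cultivars) < 1L) stop_config("cultivars", "must be nonempty")
  if (length(seasons) < 1L) stop_config("seasons", "must be nonempty")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  bms_effect <- check_number(bms_effect, "bms_effect")
  nonlin_scale <- check_number(nonlin_scale, "nonlin_scale", min = 0, max = 1)
  if (length(minor_effects)) {
    bad <- setdiff(names(minor_effects), leafq_predictors)
    if (length(bad) || is.null(names(minor_effects))) {
      stop_config("minor_effects",
                  sprintf("names must be among the 7 predictors (offending: %s)",
                          paste(bad, collapse = ", ")))
    }
  }
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(n_per_cultivar = n_per_cultivar, cultivars = as.character(cultivars),
         seasons = as.character(seasons), noise_sd = noise_sd,
         bms_effect = bms_effect, minor_effects = minor_effects,
         nonlin_scale = nonlin_scale, seed = seed),
    class = "generator_config"
  )
}

#' Generate a tobacco-like dataset
#'
#' Draws the 7 predictors from truncated normal profiles whose means differ
#' by cultivar and season (cultivar differences are mean shifts only), then
#' builds the quality response on the z-score scale as
#' `bms_effect * driver(bms) + sum(minor_effects * z(chem)) + noise`, where
#' `driver` combines a linear and a saturating (tanh) term in blue mold
#' severity and the deterministic part is standardized to unit variance.
#' Higher `|bms_effect|` than any minor effect gives the dominant-disease
#' structure the sensitivity analysis assumes.
#'
#' @param config A [generator_config()].
#' @return A data frame of class `leafq_dataset` with columns
#'   `bms, chl, n, s, nt, cl, k, quality, cultivar, season`.
#' @export
#' @examples
#' d <- generate_tobacco_like(generator_config(seed = 1))
#' nrow(d) # 400
generate_tobacco_like <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    stop_config("config", "must be a generator_config object")
  }
  set.seed(config$seed)
  cults <- config$cultivars
  seas <- config$seasons
  n_profiles_c <- names(leafq_profile_means[[1L]])
  rows <- vector("list", length(cults))
  for (ci in seq_along(cults)) {
    # recycle the four built-in cultivar profiles over custom labels
    prof_c <- n_profiles_c[(ci - 1L) %% length(n_profiles_c) + 1L]
    season_lab <- rep(seas, length.out = config$n_per_cultivar)
    X <- matrix(NA_real_, config$n_per_cultivar, length(leafq_predictors),
                dimnames = list(NULL, leafq_predictors))
    for (si in seq_along(seas)) {
      idx <- which(season_lab == seas[si])
      prof_s <- as.character((si - 1L) %% 2L + 1L)
      mu <- leafq_profile_means[[prof_s]][[prof_c]]
      for (v in leafq_predictors) {
        raw <- stats::rnorm(length(idx), mu[[v]], leafq_profile_sds[[v]])
        rng <- leafq_ranges[[v]]
        X[idx, v] <- pmin(pmax(raw, rng[1L]), rng[2L])
      }
    }
    rows[[ci]] <- data.frame(X, cultivar = cults[ci], season = season_lab,
                             stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  Z <- scale(as.matrix(d[leafq_predictors]))
  Z[, apply(as.matrix(d[leafq_predictors]), 2, stats::sd) == 0] <- 0
  # strongly saturating disease-damage response: quality loss levels off at
  # high severity, so the driver is mostly the tanh term
  driver <- (1 - config$nonlin_scale) * Z[, "bms"] +
    config$nonlin_scale * tanh(2 * Z[, "bms"])
  signal <- config$bms_effect * driver
  for (v in names(config$minor_effects)) {
    signal <- signal + config$minor_effects[[v]] * Z[, v]
  }
  if (stats::sd(signal) > 0) {
    signal <- (signal - mean(signal)) / stats::sd(signal)
  }
  quality <- signal + stats::rnorm(nrow(d), 0, config$noise_sd)
  out <- cbind(d[leafq_predictors],
               data.frame(quality = quality, cultivar = d$cultivar,
                          season = d$season, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("leafq_dataset", "data.frame")
  out
}

#' Extract the predictor matrix of a dataset
#'
#' @param data A `leafq_dataset` (or any data frame with the 7 predictor
#'   columns `bms, chl, n, s, nt, cl, k`).
#' @return Numeric matrix with the 7 predictor columns in fixed order.
#' @export
predictor_matrix <- function(data) {
  missing_cols <- setdiff(leafq_predictors, names(data))
  if (length(missing_cols)) {
    stop("data is missing predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.matrix(data[leafq_predictors])
}

#' Read/write a dataset as CSV
#'
#' The on-disk format is a plain CSV with header
#' `bms,chl,n,s,nt,cl,k,quality,cultivar,season`.
#'
#' @param data A `leafq_dataset`.
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `leafq_dataset`.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(leafq_predictors, "quality", "cultivar", "season")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- d[need]
  d$cultivar <- as.character(d$cultivar)
  d$season <- as.character(d$season)
  class(d) <- c("leafq_dataset", "data.frame")
  d
}

#' Generate data from a known ("teacher") perceptron
#'
#' Draws inputs uniformly on \[-1, 1\]^`n_inputs` and teacher weights/biases
#' uniformly on \[-1, 1\], computes the response by the exact tansig forward
#' pass, and adds Gaussian noise.  Because the generating parameters are
#' returned, fit-recovery of the GA trainer can be tested against a known
#' optimum (training RMSE 0 is attainable when `noise_sd = 0`).
#'
#' @param n_inputs,n_hidden Teacher architecture (both >= 1).
#' @param n_samples Number of rows (>= 2).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return A list of class `teacher_data` with elements `X` (matrix), `y`
#'   (vector) and `params` (the generating [mlp_parameters()]).
#' @export
generate_teacher_mlp <- function(n_inputs, n_hidden, n_samples,
                                 noise_sd = 0, seed = 1) {
  n_inputs <- check_count(n_inputs, "n_inputs")
  n_hidden <- check_count(n_hidden, "n_hidden")
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  X <- matrix(stats::runif(n_samples * n_inputs, -1, 1), n_samples, n_inputs,
              dimnames = list(NULL, paste0("x", seq_len(n_inputs))))
  arch <- mlp_architecture(n_inputs, n_hidden)
  genes <- stats::runif(n_genes(arch), -1, 1)
  params <- mlp_decode(genes, arch)
  y <- mlp_forward(params, X) + stats::rnorm(n_samples, 0, noise_sd)
  structure(list(X = X, y = y, params = params), class = "teacher_data")
}

#' Generate data from a known linear model
#'
#' Oracle data for the linear baselines: standard-normal predictors and
#' `y = intercept + X %*% coefficients + noise`.
#'
#' @param coefficients Numeric coefficient vector (default length 7; columns
#'   are named after the 7 leaf predictors when the length matches).
#' @param intercept Scalar intercept.
#' @param n_samples Number of rows; must exceed `length(coefficients) + 2`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @return List with elements `X` and `y`.
#' @export
generate_linear <- function(coefficients, intercept = 0, n_samples = 100,
                            noise_sd = 0, seed = 1) {
  p <- length(coefficients)
  if (p < 1L || anyNA(coefficients)) {
    stop_config("coefficients", "must be a nonempty numeric vector")
  }
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  if (n_samples <= p + 2L) {
    stop_config("n_samples",
                sprintf("must exceed the parameter count (need > %d)", p + 2L))
  }
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  cn <- if (p == 7L) leafq_predictors else paste0("x", seq_len(p))
  X <- matrix(stats::rnorm(n_samples * p), n_samples, p,
              dimnames = list(NULL, cn))
  y <- intercept + drop(X %*% coefficients) + stats::rnorm(n_samples, 0, noise_sd)
  list(X = X, y = y)
}

#' Convert between z-scored quality and market price
#'
#' The quality response is modeled on the z-score scale; these helpers map to
#' and from the original price scale (Iranian Rials per kg dry weight) using
#' a configurable mean and standard deviation whose defaults are the study's
#' reported price statistics.
#'
#' @param z,price Numeric vectors.
#' @param mean,sd Price mean and standard deviation.
#' @return Numeric vector on the other scale.
#' @export
quality_to_price <- function(z, mean = 1579996.5, sd = 452320.3) z * sd + mean

#' @rdname quality_to_price
#' @export
price_to_quality <- function(price, mean = 1579996.5, sd = 452320.3) {
  (price - mean) / sd
}
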