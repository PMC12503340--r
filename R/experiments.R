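# Reproducible study-style experiments built from the package primitives.

#' Teacher-network fit-recovery experiment
#'
#' For each seed: generate noiseless data from a random teacher perceptron,
#' hold out a test fraction, select the hidden-neuron count on the training
#' portion by cross-validated GA training, refit with the selected count, and
#' score held-out R-squared.  This is the synthetic analog of validating the
#' GA-trained perceptron on data known to be generated by such a network.
#'
#' @param seeds Integer vector; one experiment per seed.
#' @param n_inputs,n_hidden_true Teacher architecture (default 7 inputs, 5
#'   hidden tansig units).
#' @param n_samples Rows per dataset (default 100).
#' @param noise_sd Teacher noise (default 0, i.e. a realizable target).
#' @param hidden_grid Candidate hidden counts searched (default 3:7).
#' @param config A [ga_config()]; its seed is overridden per experiment.
#' @param train_frac Training fraction of the split (default 0.8).
#' @param inner_cv Folds/repeats of the hidden-count selection protocol.
#' @return Data frame with one row per seed: `seed`, `n_hidden`, `r2_test`,
#'   `refined`.
#' @export
teacher_recovery_experiment <- function(seeds, n_inputs = 7, n_hidden_true = 5,
                                        n_samples = 100, noise_sd = 0,
                                        hidden_grid = 3:7,
                                        config = ga_config(local_refinement = TRUE),
                                        train_frac = 0.8,
                                        inner_cv = list(k = 5, repeats = 1)) {
  rows <- lapply(seeds, function(s) {
    td <- generate_teacher_mlp(n_inputs, n_hidden_true, n_samples,
                               noise_sd = noise_sd, seed = s)
    set.seed(s)
    n_tr <- floor(train_frac * n_samples)
    idx <- sample.int(n_samples, n_tr)
    X_tr <- td$X[idx, , drop = FALSE]
    y_tr <- td$y[idx]
    X_te <- td$X[-idx, , drop = FALSE]
    y_te <- td$y[-idx]
    cfg <- config
    cfg$seed <- s
    sel <- search_architecture(X_tr, y_tr, hidden_grid, cfg, cv = inner_cv)
    model <- fit_mlp_ga(X_tr, y_tr, n_hidden = sel$best_n_hidden, config = cfg)
    data.frame(seed = s, n_hidden = sel$best_n_hidden,
               r2_test = r_squared(y_te, predict(model, X_te)),
               refined = model$refined)
  })
  do.call(rbind, rows)
}

#' Headline comparison: perceptron vs best linear baseline
#'
#' For each seed, generates a tobacco-like dataset (nonlinear, dominant
#' blue-mold effect), splits train/test, fits the GA-trained perceptron and
#' all five linear baselines on the training portion, and records test
#' R-squared of each.  Used to check that the nonlinear model outperforms
#' the best linear family on data with a saturating disease effect.
#'
#' @param seeds Integer vector; one dataset and split per seed.
#' @param gen_config A [generator_config()]; its seed is overridden per run.
#' @param config A [ga_config()] for the perceptron.
#' @param n_hidden Hidden-neuron count of the perceptron.
#' @param train_frac Training fraction.
#' @return Data frame with columns `seed`, `r2_mlp`, `r2_best_linear`,
#'   `best_linear`.
#' @export
headline_comparison <- function(seeds,
                                gen_config = generator_config(),
                                config = ga_config(local_refinement = TRUE),
                                n_hidden = 5, train_frac = 0.8) {
  baselines <- c("mlr", "sr", "olsr", "plsr", "pcr")
  rows <- lapply(seeds, function(s) {
    gc <- gen_config
    gc$seed <- s
    d <- generate_tobacco_like(gc)
    X <- predictor_matrix(d)
    y <- d$quality
    set.seed(s)
    idx <- sample.int(nrow(X), floor(train_frac * nrow(X)))
    cfg <- config
    cfg$seed <- s
    mlp <- fit_mlp_ga(X[idx, ], y[idx], n_hidden = n_hidden, config = cfg)
    r2_mlp <- r_squared(y[-idx], predict(mlp, X[-idx, ]))
    r2_lin <- vapply(baselines, function(m) {
      sp <- spec_baseline(m)
      fit <- sp$fit(X[idx, , drop = FALSE], y[idx])
      r_squared(y[-idx], sp$predict(fit, X[-idx, , drop = FALSE]))
    }, numeric(1))
    data.frame(seed = s, r2_mlp = r2_mlp, r2_best_linear = max(r2_lin),
               best_linear = toupper(names(which.max(r2_lin))))
  })
  do.call(rbind, rows)
}
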