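# End-to-end orchestration: generate or load data, cross-validate all six
# model families per cultivar and pooled, run the sensitivity analysis on the
# fitted perceptron, and write report tables plus a reproducibility manifest.

#' Pipeline configuration
#'
#' @param data A CSV path, a `leafq_dataset`, or a [generator_config()]
#'   (default: the standard generator seeded from `seed`).
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; all stage seeds derive from it deterministically
#'   (generator: `seed`; fold plans: `seed + 1000 + subset index`; GA:
#'   `seed + 2000 + subset index`).
#' @param models Model families to run (subset of
#'   `mlr, sr, olsr, plsr, pcr, mlp`).
#' @param ga A [ga_config()] for the perceptron stages.  The demo default
#'   uses 100 generations with local refinement so a full run stays fast;
#'   pass `ga_config(generations = 500)` for the full protocol.
#' @param n_hidden Hidden-neuron count, or `NULL` to search `hidden_grid`.
#' @param hidden_grid Candidate counts when `n_hidden` is `NULL`.
#' @param cv List with `k` and `repeats` of the evaluation protocol
#'   (default five folds, ten repeats).
#' @param boxcox Box-Cox-normalize predictors inside each training fold.
#' @param per_cultivar Also run each cultivar's subset separately.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(data = NULL, outdir = tempfile("leafqnn-run-"),
                            seed = 1,
                            models = c("mlr", "sr", "olsr", "plsr", "pcr", "mlp"),
                            ga = ga_config(generations = 100,
                                           local_refinement = TRUE),
                            n_hidden = 5, hidden_grid = 3:7,
                            cv = list(k = 5, repeats = 10),
                            boxcox = TRUE, per_cultivar = TRUE) {
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  models <- match.arg(models, c("mlr", "sr", "olsr", "plsr", "pcr", "mlp"),
                      several.ok = TRUE)
  if (is.null(data)) data <- generator_config(seed = seed)
  structure(
    list(data = data, outdir = outdir, seed = seed, models = models, ga = ga,
         n_hidden = n_hidden, hidden_grid = hidden_grid, cv = cv,
         boxcox = isTRUE(boxcox), per_cultivar = isTRUE(per_cultivar)),
    class = "pipeline_config"
  )
}

pipeline_load_data <- function(config) {
  d <- config$data
  if (is.character(d)) return(read_dataset_csv(d))
  if (inherits(d, "leafq_dataset")) return(d)
  if (inherits(d, "generator_config")) return(generate_tobacco_like(d))
  stop("unsupported 'data' field in pipeline configuration", call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the dataset; (optionally) screen it for PCA
#' outliers; for the pooled data and each cultivar subset, cross-validate
#' every requested model family and fit the perceptron on all subset rows for
#' the VSE/VSR sensitivity analysis; write the performance table
#' (`table1_metrics.csv/json`), the importance table
#' (`table2_sensitivity.csv/json`), GA convergence traces
#' (`ga_trace_<subset>.csv`), fitted perceptrons (`mlp_<subset>.json`), the
#' model comparison (`comparison.csv`) and a manifest (`manifest.json`).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `metrics`, `sensitivity`, `comparison`,
#'   `outliers`, `manifest` and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  data <- pipeline_load_data(config)
  write_dataset_csv(data, file.path(config$outdir, "dataset.csv"))

  outliers <- pca_outlier_screen(predictor_matrix(data))
  subsets <- list(all = data)
  if (config$per_cultivar) {
    for (cult in unique(data$cultivar)) {
      subsets[[cult]] <- data[data$cultivar == cult, , drop = FALSE]
    }
  }

  preprocess <- if (config$boxcox) list(boxcox = TRUE) else NULL
  metric_rows <- list()
  sens_cols <- list()
  for (si in seq_along(subsets)) {
    sub_name <- names(subsets)[si]
    sub <- subsets[[si]]
    X <- predictor_matrix(sub)
    y <- sub$quality
    plan <- make_fold_plan(nrow(X), k = config$cv$k %||% 5,
                           repeats = config$cv$repeats %||% 10,
                           seed = config$seed + 1000L + si)
    ga_cfg <- config$ga
    ga_cfg$seed <- config$seed + 2000L + si
    n_hidden <- config$n_hidden
    if ("mlp" %in% config$models && is.null(n_hidden)) {
      n_hidden <- search_architecture(X, y, config$hidden_grid, ga_cfg,
                                      cv = list(k = config$cv$k %||% 5,
                                                repeats = 1))$best_n_hidden
    }
    for (m in config$models) {
      spec <- if (m == "mlp") {
        spec_mlp_ga(n_hidden = n_hidden, config = ga_cfg)
      } else {
        spec_baseline(m)
      }
      res <- cross_validate(spec, X, y, plan, preprocess = preprocess)
      for (rec in list(res$training, res$testing)) {
        rec$subset_data <- sub_name
        rec$n_hidden <- if (m == "mlp") n_hidden else NA_integer_
        metric_rows[[length(metric_rows) + 1L]] <- rec
      }
    }
    if ("mlp" %in% config$models) {
      full <- fit_mlp_ga(X, y, n_hidden = n_hidden, config = ga_cfg)
      report <- build_sensitivity_report(full, X, y)
      tab <- report$table
      sens_cols[[sub_name]] <- stats::setNames(tab$vsr_rescaled, tab$variable)
      utils::write.csv(
        data.frame(generation = seq_along(full$trace), best_rmse = full$trace),
        file.path(config$outdir, paste0("ga_trace_", sub_name, ".csv")),
        row.names = FALSE)
      write_mlp_json(full$params,
                     file.path(config$outdir, paste0("mlp_", sub_name, ".json")))
    }
  }

  metrics <- do.call(rbind, metric_rows)
  metrics <- metrics[, c("subset_data", "model", "n_hidden", "subset",
                         "r2", "rmse", "mape")]
  names(metrics)[4] <- "partition"
  utils::write.csv(metrics, file.path(config$outdir, "table1_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics, file.path(config$outdir, "table1_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  sensitivity <- NULL
  if (length(sens_cols)) {
    vars <- leafq_predictors
    sensitivity <- data.frame(variable = vars,
                              lapply(sens_cols, function(v) v[vars]),
                              check.names = FALSE, row.names = NULL)
    utils::write.csv(sensitivity,
                     file.path(config$outdir, "table2_sensitivity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sensitivity,
                         file.path(config$outdir, "table2_sensitivity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  comparison <- NULL
  if (length(config$models) >= 2L) {
    comparison <- compare_models(metrics)
    utils::write.csv(comparison, file.path(config$outdir, "comparison.csv"),
                     row.names = FALSE)
  }

  config_path <- file.path(config$outdir, "config.json")
  cfg_serializable <- config
  cfg_serializable$outdir <- NULL # run-local path; kept out of the hash
  cfg_serializable$data <- if (is.character(config$data)) {
    config$data
  } else if (inherits(config$data, "generator_config")) {
    unclass(config$data)
  } else {
    class(config$data)[1L]
  }
  jsonlite::write_json(lapply(unclass(cfg_serializable), unclass), config_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    config_hash = unname(tools::md5sum(config_path)),
    seed = config$seed,
    n_rows = nrow(data),
    subsets = names(subsets),
    models = config$models,
    outliers_flagged = sum(outliers),
    package_version = as.character(utils::packageVersion("leafqnn")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, sensitivity = sensitivity,
                 comparison = comparison, outliers = outliers,
                 manifest = manifest, outdir = config$outdir))
}

#' Compare the perceptron against the best regression family
#'
#' For each data subset in a metrics table, finds the regression family with
#' the highest testing R-squared and contrasts it with the perceptron.  Exact
#' ties are reported as a comma-joined list of winners.
#'
#' @param metrics A metrics data frame as produced by [run_pipeline()]
#'   (columns `subset_data, model, partition, r2, ...`).
#' @return Data frame with one row per subset: best regression, its testing
#'   R-squared, the perceptron's, and the winner.
#' @export
compare_models <- function(metrics) {
  need <- c("subset_data", "model", "partition", "r2")
  if (!all(need %in% names(metrics))) {
    stop("metrics table lacks required columns", call. = FALSE)
  }
  test <- metrics[metrics$partition == "testing", , drop = FALSE]
  if (length(unique(test$model)) < 2L) {
    stop("need testing metrics for at least two models", call. = FALSE)
  }
  rows <- lapply(split(test, test$subset_data), function(sub) {
    lin <- sub[sub$model != "MLPNN-GA", , drop = FALSE]
    mlp <- sub[sub$model == "MLPNN-GA", , drop = FALSE]
    best_lin <- lin[which(lin$r2 == max(lin$r2)), , drop = FALSE]
    r2_mlp <- if (nrow(mlp)) mlp$r2[1L] else NA_real_
    winner <- if (!nrow(mlp)) {
      paste(best_lin$model, collapse = ",")
    } else if (r2_mlp > max(lin$r2)) {
      "MLPNN-GA"
    } else if (r2_mlp == max(lin$r2)) {
      paste(c("MLPNN-GA", best_lin$model), collapse = ",")
    } else {
      paste(best_lin$model, collapse = ",")
    }
    data.frame(subset_data = sub$subset_data[1L],
               best_regression = paste(best_lin$model, collapse = ","),
               r2_best_regression = max(lin$r2), r2_mlp = r2_mlp,
               winner = winner, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
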