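# Real-coded genetic algorithm that trains the perceptron by minimizing
# training RMSE over flat weight/bias chromosomes: roulette-wheel selection,
# single-point crossover, per-gene uniform-reset mutation, elitism, and an
# optional gradient polish of the best chromosome.

#' Genetic-algorithm configuration
#'
#' Defaults follow the study settings: population 50, crossover rate 0.85,
#' mutation rate 0.01, 500 generations.  Elitism (1 individual) is an
#' extension guaranteeing a non-increasing best-fitness trace; set
#' `elitism_count = 0` to disable it.  `local_refinement` appends a bounded
#' BFGS polish (analytic gradient) of the best chromosome after the GA; runs
#' that use it are flagged in their results.
#'
#' @param population_size Chromosomes per generation (>= 2).
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-gene probability of uniform reset.
#' @param generations Number of evaluated generations (>= 1).
#' @param gene_range Length-2 interval from which genes are drawn.
#' @param elitism_count Best chromosomes copied unchanged each generation.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param local_refinement Logical; polish the GA optimum by BFGS.
#' @param refine_maxit Iteration cap of the polish.
#' @param selection `"roulette"` (score 1/(RMSE + 1e-12)) or `"rank"`.
#' @param crossover `"single_point"` or `"blend"` (arithmetic).
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.85,
                      mutation_rate = 0.01, generations = 500,
                      gene_range = c(-1, 1), elitism_count = 1,
                      seed = NULL, local_refinement = FALSE,
                      refine_maxit = 200,
                      selection = c("roulette", "rank"),
                      crossover = c("single_point", "blend")) {
  population_size <- check_count(population_size, "population_size", min = 2)
  crossover_rate <- check_number(crossover_rate, "crossover_rate", 0, 1)
  mutation_rate <- check_number(mutation_rate, "mutation_rate", 0, 1)
  generations <- check_count(generations, "generations")
  if (!is.numeric(gene_range) || length(gene_range) != 2L ||
      gene_range[2L] < gene_range[1L]) {
    stop_config("gene_range", "must be a nondecreasing length-2 interval")
  }
  elitism_count <- check_count(elitism_count, "elitism_count", min = 0)
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  refine_maxit <- check_count(refine_maxit, "refine_maxit")
  structure(
    list(population_size = population_size, crossover_rate = crossover_rate,
         mutation_rate = mutation_rate, generations = generations,
         gene_range = as.numeric(gene_range), elitism_count = elitism_count,
         seed = seed, local_refinement = isTRUE(local_refinement),
         refine_maxit = refine_maxit, selection = match.arg(selection),
         crossover = match.arg(crossover)),
    class = "ga_config"
  )
}

new_chromosome <- function(genes, fitness = NA_real_) {
  structure(list(genes = genes, fitness = fitness), class = "chromosome")
}

#' Random initial population
#'
#' Genes are drawn i.i.d. uniform on `gene_range`; reproducible from
#' `config$seed` when set.
#'
#' @param arch An [mlp_architecture()].
#' @param config A [ga_config()].
#' @return List of `population_size` chromosomes (`genes`, unset `fitness`).
#' @export
init_population <- function(arch, config = ga_config()) {
  stopifnot(inherits(arch, "mlp_architecture"), inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- n_genes(arch)
  lapply(seq_len(config$population_size), function(i) {
    new_chromosome(stats::runif(L, config$gene_range[1L], config$gene_range[2L]))
  })
}

#' Chromosome fitness: training RMSE
#'
#' Decodes the gene vector, runs the forward pass on every training row, and
#' returns the RMSE against the (scaled) training response.  Lower is better.
#'
#' @param genes Numeric gene vector (or a chromosome).
#' @param arch An [mlp_architecture()].
#' @param X_train,y_train Training data on the network scale.
#' @return Nonnegative RMSE.
#' @export
ga_fitness <- function(genes, arch, X_train, y_train) {
  if (inherits(genes, "chromosome")) genes <- genes$genes
  stopifnot(inherits(arch, "mlp_architecture"))
  if (length(genes) != n_genes(arch)) {
    stop(sprintf("gene vector has length %d; architecture requires %d",
                 length(genes), n_genes(arch)), call. = FALSE)
  }
  if (!is.matrix(X_train) || ncol(X_train) != arch$n_inputs ||
      nrow(X_train) != length(y_train)) {
    stop("training data shapes are inconsistent with the architecture",
         call. = FALSE)
  }
  pred <- mlp_forward_genes(genes, arch$n_inputs, arch$n_hidden, X_train)
  sqrt(mean((pred - y_train)^2))
}

# Selection scores for RMSE minimization: roulette slices are proportional
# to 1/(RMSE + eps); the rank variant uses linear rank weights.
selection_scores <- function(fitness, method = "roulette", eps = 1e-12) {
  if (any(is.na(fitness))) {
    stop("all fitness values must be evaluated before selection",
         call. = FALSE)
  }
  s <- switch(method,
              roulette = 1 / (fitness + eps),
              rank = length(fitness) + 1 - rank(fitness, ties.method = "average"))
  s / sum(s)
}

#' Roulette-wheel selection
#'
#' Samples `k` chromosomes with replacement; selection probability is
#' proportional to `1 / (RMSE + 1e-12)`, so lower training error means a
#' larger wheel slice.
#'
#' @param population List of chromosomes with evaluated `fitness`.
#' @param k Number of draws.
#' @return List of `k` selected chromosomes.
#' @export
roulette_select <- function(population, k) {
  k <- check_count(k, "k", min = 0)
  if (k == 0L) return(list())
  fitness <- vapply(population, function(ch) ch$fitness, numeric(1))
  probs <- selection_scores(fitness)
  population[sample.int(length(population), k, replace = TRUE, prob = probs)]
}

#' Single-point crossover
#'
#' With probability `rate`, picks a uniform cut point and swaps tails;
#' otherwise the children are copies of the parents.  Either way the combined
#' gene multiset of the children equals that of the parents.
#'
#' @param a,b Parent gene vectors of equal length.
#' @param rate Crossover probability.
#' @return List of two child gene vectors.
#' @export
crossover_single_point <- function(a, b, rate = 0.85) {
  if (length(a) != length(b)) {
    stop("parent gene vectors must have equal length", call. = FALSE)
  }
  L <- length(a)
  if (L > 1L && stats::runif(1) < rate) {
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    child_a <- c(a[seq_len(cut)], b[tail_idx])
    child_b <- c(b[seq_len(cut)], a[tail_idx])
    list(child_a, child_b)
  } else {
    list(a, b)
  }
}

# Arithmetic (blend) crossover: children are complementary convex
# combinations with a uniform mixing weight.
crossover_blend <- function(a, b, rate = 0.85) {
  if (length(a) != length(b)) {
    stop("parent gene vectors must have equal length", call. = FALSE)
  }
  if (stats::runif(1) < rate) {
    alpha <- stats::runif(1)
    list(alpha * a + (1 - alpha) * b, (1 - alpha) * a + alpha * b)
  } else {
    list(a, b)
  }
}

#' Uniform-reset mutation
#'
#' Each gene is independently replaced, with probability `rate`, by a fresh
#' uniform draw from `gene_range`; the expected number of mutated genes is
#' `rate * length(genes)`.
#'
#' @param genes Gene vector.
#' @param rate Per-gene mutation probability.
#' @param gene_range Length-2 interval.
#' @return Mutated gene vector.
#' @export
mutate_uniform <- function(genes, rate = 0.01, gene_range = c(-1, 1)) {
  hit <- stats::runif(length(genes)) < rate
  if (any(hit)) {
    genes[hit] <- stats::runif(sum(hit), gene_range[1L], gene_range[2L])
  }
  genes
}

#' Evolve perceptron weights by the genetic algorithm
#'
#' Runs initialize -> evaluate -> select -> crossover -> mutate -> replace
#' (with elitism) for `generations` evaluated populations and returns the
#' best-ever chromosome decoded to [mlp_parameters()], with the
#' per-generation best-RMSE trace.  With `elitism_count >= 1` the trace is
#' non-increasing.  If `config$local_refinement`, a bounded BFGS polish of
#' the best chromosome follows and is flagged in the result.
#'
#' @param arch An [mlp_architecture()].
#' @param X_train Training inputs on the network scale (rows in \[-1, 1\]).
#' @param y_train Training targets inside (-1, 1).
#' @param config A [ga_config()].
#' @return A `ga_result`: `best_params`, `best_genes`,
#'   `best_rmse_per_generation`, `final_fitness`, `evaluations`, `refined`.
#' @export
ga_evolve <- function(arch, X_train, y_train, config = ga_config()) {
  stopifnot(inherits(arch, "mlp_architecture"), inherits(config, "ga_config"))
  X_train <- check_matrix(X_train, "X_train")
  if (nrow(X_train) == 0L || length(y_train) != nrow(X_train)) {
    stop("training data must be nonempty with matching response length",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ni <- arch$n_inputs
  nh <- arch$n_hidden
  L <- n_genes(arch)
  P <- config$population_size
  lo <- config$gene_range[1L]
  hi <- config$gene_range[2L]
  eval_rmse <- function(genes) {
    pred <- mlp_forward_genes(genes, ni, nh, X_train)
    sqrt(mean((pred - y_train)^2))
  }
  cross_fun <- if (config$crossover == "single_point") {
    crossover_single_point
  } else {
    crossover_blend
  }

  pop <- matrix(stats::runif(P * L, lo, hi), P, L)
  fitness <- apply(pop, 1, eval_rmse)
  evaluations <- P
  trace <- numeric(config$generations)
  best_i <- which.min(fitness)
  best_genes <- pop[best_i, ]
  best_fit <- fitness[best_i]

  for (g in seq_len(config$generations)) {
    gen_best <- which.min(fitness)
    if (fitness[gen_best] < best_fit) {
      best_fit <- fitness[gen_best]
      best_genes <- pop[gen_best, ]
    }
    trace[g] <- fitness[gen_best]
    if (g == config$generations) break

    newpop <- matrix(NA_real_, P, L)
    new_fit <- rep(NA_real_, P)
    ne <- min(config$elitism_count, P)
    if (ne > 0L) {
      elite <- order(fitness)[seq_len(ne)]
      newpop[seq_len(ne), ] <- pop[elite, , drop = FALSE]
      new_fit[seq_len(ne)] <- fitness[elite]
    }
    probs <- selection_scores(fitness, config$selection)
    i <- ne
    while (i < P) {
      parents <- sample.int(P, 2L, replace = TRUE, prob = probs)
      children <- cross_fun(pop[parents[1L], ], pop[parents[2L], ],
                            config$crossover_rate)
      for (child in children) {
        if (i >= P) break
        i <- i + 1L
        newpop[i, ] <- mutate_uniform(child, config$mutation_rate,
                                      config$gene_range)
      }
    }
    recompute <- which(is.na(new_fit))
    new_fit[recompute] <- apply(newpop[recompute, , drop = FALSE], 1, eval_rmse)
    evaluations <- evaluations + length(recompute)
    pop <- newpop
    fitness <- new_fit
  }

  refined <- FALSE
  if (config$local_refinement) {
    polished <- ga_local_refine(best_genes, arch, X_train, y_train,
                                maxit = config$refine_maxit)
    polished_fit <- eval_rmse(polished)
    evaluations <- evaluations + 1L
    if (polished_fit < best_fit) {
      best_genes <- polished
      best_fit <- polished_fit
      refined <- TRUE
    }
  }

  structure(
    list(best_params = mlp_decode(best_genes, arch), best_genes = best_genes,
         best_rmse_per_generation = trace, final_fitness = best_fit,
         evaluations = evaluations, refined = refined, config = config),
    class = "ga_result"
  )
}

#' Gradient polish of a chromosome
#'
#' Minimizes the training mean squared error from a given gene vector by
#' BFGS with the exact backpropagation gradient, capped at `maxit`
#' iterations.  Used as the optional post-GA refinement step.
#'
#' @param genes Starting gene vector.
#' @param arch An [mlp_architecture()].
#' @param X_train,y_train Training data on the network scale.
#' @param maxit Iteration cap.
#' @return The refined gene vector.
#' @export
ga_local_refine <- function(genes, arch, X_train, y_train, maxit = 200) {
  ni <- arch$n_inputs
  nh <- arch$n_hidden
  res <- stats::optim(
    genes,
    fn = function(g) {
      mean((mlp_forward_genes(g, ni, nh, X_train) - y_train)^2)
    },
    gr = function(g) mlp_mse_grad(g, ni, nh, X_train, y_train),
    method = "BFGS",
    control = list(maxit = maxit, reltol = 1e-12)
  )
  res$par
}

#' Fit a GA-trained perceptron to raw data
#'
#' Range-scales every predictor column to \[-1, 1\] and the response to
#' \[-0.9, 0.9\] (the tansig output neuron is bounded in (-1, 1); the margin
#' avoids saturation), runs [ga_evolve()], and returns a predictor whose
#' outputs are mapped back to the original response scale.
#'
#' @param X Predictor matrix (original units).
#' @param y Response vector (original scale).
#' @param n_hidden Hidden-neuron count.
#' @param config A [ga_config()].
#' @return An `mlp_ga_model` with a [predict()][predict.mlp_ga_model] method.
#' @export
fit_mlp_ga <- function(X, y, n_hidden = 5, config = ga_config()) {
  X <- check_matrix(X)
  arch <- mlp_architecture(ncol(X), n_hidden)
  x_scalers <- lapply(seq_len(ncol(X)), function(j) range_fit(X[, j], -1, 1))
  Xs <- vapply(seq_len(ncol(X)),
               function(j) range_apply(X[, j], x_scalers[[j]], warn = FALSE),
               numeric(nrow(X)))
  Xs <- matrix(Xs, nrow = nrow(X), dimnames = dimnames(X))
  y_scaler <- range_fit(y, -0.9, 0.9)
  ys <- range_apply(y, y_scaler, warn = FALSE)
  ga <- ga_evolve(arch, Xs, ys, config)
  structure(
    list(arch = arch, params = ga$best_params, x_scalers = x_scalers,
         x_names = colnames(X), y_scaler = y_scaler,
         trace = ga$best_rmse_per_generation, refined = ga$refined,
         final_fitness = ga$final_fitness, evaluations = ga$evaluations),
    class = "mlp_ga_model"
  )
}

#' Predict from a GA-trained perceptron
#'
#' @param object An `mlp_ga_model` from [fit_mlp_ga()].
#' @param newdata Predictor matrix on the original scale; out-of-range values
#'   are clamped to the training range.
#' @param ... Unused.
#' @return Predicted response on the original scale.
#' @export
predict.mlp_ga_model <- function(object, newdata, ...) {
  newdata <- check_matrix(newdata, "newdata")
  if (!is.null(object$x_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$x_names, drop = FALSE]
  }
  if (ncol(newdata) != object$arch$n_inputs) {
    stop("'newdata' has the wrong number of predictor columns", call. = FALSE)
  }
  Xs <- vapply(seq_len(ncol(newdata)),
               function(j) range_apply(newdata[, j], object$x_scalers[[j]],
                                       warn = FALSE),
               numeric(nrow(newdata)))
  Xs <- matrix(Xs, nrow = nrow(newdata))
  range_invert(mlp_forward(object$params, Xs), object$y_scaler)
}

#' Select the hidden-neuron count by cross-validation
#'
#' Runs the GA trainer for every candidate hidden-neuron count under a
#' k-fold protocol and picks the count with the lowest mean test RMSE, ties
#' broken toward fewer neurons.
#'
#' @param X,y Data on the original scale.
#' @param hidden_counts Candidate counts (default 1:10).
#' @param config A [ga_config()]; fold-level GA seeds are derived from
#'   `config$seed`.
#' @param cv List with `k` and `repeats` of the selection protocol.
#' @return List with `best_n_hidden` and a `table` data frame
#'   (`n_hidden`, `cv_rmse`).
#' @export
search_architecture <- function(X, y, hidden_counts = 1:10,
                                config = ga_config(),
                                cv = list(k = 5, repeats = 1)) {
  X <- check_matrix(X)
  if (length(hidden_counts) < 1L) {
    stop_config("hidden_counts", "must be nonempty")
  }
  hidden_counts <- sort(unique(as.integer(hidden_counts)))
  base_seed <- config$seed %||% 1L
  plan <- make_fold_plan(nrow(X), k = cv$k %||% 5, repeats = cv$repeats %||% 1,
                         seed = base_seed)
  cv_rmse <- vapply(seq_along(hidden_counts), function(i) {
    h <- hidden_counts[i]
    cfg <- config
    cfg$seed <- (base_seed + 101L * h) %% .Machine$integer.max
    res <- cross_validate(spec_mlp_ga(n_hidden = h, config = cfg), X, y, plan)
    res$testing$rmse
  }, numeric(1))
  best <- hidden_counts[which.min(cv_rmse)]
  list(best_n_hidden = best,
       table = data.frame(n_hidden = hidden_counts, cv_rmse = cv_rmse))
}
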