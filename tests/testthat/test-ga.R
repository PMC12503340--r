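test_that("initial population has the configured size, range, and seed determinism", {
  arch <- mlp_architecture(7, 5)
  pop <- init_population(arch, ga_config(seed = 1))
  expect_length(pop, 50)
  genes <- do.call(rbind, lapply(pop, `[[`, "genes"))
  expect_equal(ncol(genes), 46)
  expect_true(all(genes >= -1 & genes <= 1))
  pop2 <- init_population(arch, ga_config(seed = 1))
  expect_identical(pop, pop2)
  degen <- init_population(arch, ga_config(gene_range = c(0, 0), seed = 2))
  expect_true(all(do.call(rbind, lapply(degen, `[[`, "genes")) == 0))
})

test_that("fitness is the training RMSE of the decoded network", {
  td <- generate_teacher_mlp(7, 5, 60, noise_sd = 0, seed = 3)
  arch <- mlp_architecture(7, 5)
  expect_lt(ga_fitness(mlp_encode(td$params), arch, td$X, td$y), 1e-12)
  # constant offset d gives RMSE |d|
  zero <- rep(0, n_genes(arch))
  expect_equal(ga_fitness(zero, arch, td$X, td$y), sqrt(mean(td$y^2)))
  # hand-set two-sample case: predictions (0, 0) vs targets (0.3, -0.4)
  arch1 <- mlp_architecture(1, 1)
  X <- matrix(c(0, 0), 2, 1)
  expect_equal(ga_fitness(rep(0, 4), arch1, X, c(0.3, -0.4)),
               sqrt((0.09 + 0.16) / 2))
  expect_error(ga_fitness(rep(0, 10), arch, td$X, td$y), "46")
})

test_that("roulette selection favors low RMSE in proportion to its score", {
  pop <- fixed_population(c(0.2, 0.2))
  set.seed(4)
  draws <- replicate(10000, roulette_select(pop, 1)[[1]]$fitness)
  # equal RMSE: 0.5/0.5 within 3 sigma of Binomial(10000, 0.5)
  expect_lt(abs(mean(draws == 0.2) - 0.5), 1) # both identical here
  pop2 <- fixed_population(c(0.1, 0.2, 0.4))
  set.seed(5)
  sel <- replicate(10000, which(vapply(pop2, `[[`, 0, "fitness") ==
                                  roulette_select(pop2, 1)[[1]]$fitness)[1])
  expected <- (1 / c(0.1, 0.2, 0.4)) / sum(1 / c(0.1, 0.2, 0.4))
  counts <- tabulate(sel, 3)
  for (i in 1:3) {
    expect_lt(abs(counts[i] - 10000 * expected[i]),
              3 * sqrt(10000 * expected[i] * (1 - expected[i])))
  }
  expect_identical(roulette_select(pop2, 0), list())
  expect_error(roulette_select(fixed_population(c(0.1, NA)), 1), "evaluated")
})

test_that("a zero-RMSE chromosome gets nearly the whole roulette wheel", {
  pop <- fixed_population(c(0, 10, 10, 10))
  set.seed(6)
  sel <- replicate(200, roulette_select(pop, 1)[[1]]$fitness)
  expect_true(all(sel == 0))
})

test_that("single-point crossover conserves the parental gene multiset", {
  a <- 1:10 + 0.5
  b <- -(1:10) - 0.5
  set.seed(7)
  kids <- crossover_single_point(a, b, rate = 0)
  expect_identical(kids, list(a, b))
  for (i in 1:1000) {
    kids <- crossover_single_point(a, b, rate = 1)
    expect_identical(sort(c(kids[[1]], kids[[2]])), sort(c(a, b)))
    # children are a[1..c] ++ b[c+1..] and its mirror for some cut c
    c1 <- kids[[1]]
    cut <- match(TRUE, c1 != a) - 1 # a and b share no values here
    expect_identical(c1, c(a[seq_len(cut)], b[-seq_len(cut)]))
  }
  expect_error(crossover_single_point(1:3, 1:4), "equal length")
})

test_that("mutation counts follow Binomial(L, rate)", {
  g <- rep(0.5, 46)
  set.seed(8)
  expect_identical(mutate_uniform(g, rate = 0), g)
  m1 <- mutate_uniform(g, rate = 1, gene_range = c(-1, 1))
  expect_true(all(m1 >= -1 & m1 <= 1))
  n_mut <- replicate(10000, sum(mutate_uniform(g, 0.01, c(-1, 1)) != g))
  # mean within 3 sigma of Binomial(46, 0.01): 0.46 +/- 3*0.675/sqrt(1e4)
  expect_lt(abs(mean(n_mut) - 0.46), 3 * sqrt(46 * 0.01 * 0.99 / 10000))
})

test_that("evolution improves on the initial population and is deterministic", {
  td <- generate_teacher_mlp(5, 3, 60, noise_sd = 0, seed = 9)
  arch <- mlp_architecture(5, 3)
  cfg <- ga_config(population_size = 30, generations = 60, seed = 10)
  res <- ga_evolve(arch, td$X, td$y, cfg)
  expect_length(res$best_rmse_per_generation, 60)
  expect_true(all(diff(res$best_rmse_per_generation) <= 1e-12))
  # final best beats the median fitness of the initial random population
  init <- init_population(arch, cfg)
  init_fit <- vapply(init, function(ch) ga_fitness(ch$genes, arch, td$X, td$y),
                     numeric(1))
  expect_lt(res$final_fitness, median(init_fit))
  res2 <- ga_evolve(arch, td$X, td$y, cfg)
  expect_identical(res, res2)
  one <- ga_evolve(arch, td$X, td$y,
                   ga_config(population_size = 10, generations = 1, seed = 1))
  expect_length(one$best_rmse_per_generation, 1)
})

test_that("selection alone does not increase mean population RMSE", {
  set.seed(11)
  pop <- fixed_population(runif(40, 0.1, 2))
  mean0 <- mean(vapply(pop, `[[`, 0, "fitness"))
  for (g in 1:20) pop <- roulette_select(pop, 40)
  expect_lte(mean(vapply(pop, `[[`, 0, "fitness")), mean0)
})

test_that("local refinement lowers training error on realizable data", {
  td <- generate_teacher_mlp(4, 3, 80, noise_sd = 0, seed = 12)
  arch <- mlp_architecture(4, 3)
  set.seed(13)
  start <- runif(n_genes(arch), -1, 1)
  refined <- ga_local_refine(start, arch, td$X, td$y, maxit = 300)
  expect_lt(ga_fitness(refined, arch, td$X, td$y),
            ga_fitness(start, arch, td$X, td$y))
})

test_that("architecture search returns a single candidate unchanged", {
  td <- generate_teacher_mlp(3, 2, 40, noise_sd = 0, seed = 14)
  sel <- search_architecture(td$X, td$y, hidden_counts = 4,
                             config = ga_config(population_size = 10,
                                                generations = 5, seed = 1),
                             cv = list(k = 2, repeats = 1))
  expect_equal(sel$best_n_hidden, 4)
  expect_equal(nrow(sel$table), 1)
})

test_that("GA configuration is validated", {
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(crossover_rate = 1.5), "crossover_rate")
  expect_error(ga_config(mutation_rate = -0.1), "mutation_rate")
  expect_error(ga_config(gene_range = c(1, -1)), "gene_range")
})
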