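# Shared fixtures, built in code at test time.

random_params <- function(n_inputs, n_hidden, seed = 1) {
  set.seed(seed)
  arch <- mlp_architecture(n_inputs, n_hidden)
  mlp_decode(runif(n_genes(arch), -1, 1), arch)
}

# A population of evaluated chromosomes with prescribed fitness values.
fixed_population <- function(fitness, L = 4L) {
  lapply(fitness, function(f) {
    ch <- list(genes = rep(0, L), fitness = f)
    class(ch) <- "chromosome"
    ch
  })
}

skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}
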