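# leafqnn

Predicting tobacco (*Nicotiana tabacum*) leaf quality from leaf chemistry
and disease pressure with a GA-trained multilayer perceptron, benchmarked
against five linear regression families, with ablation-based variable
importance.

## The problem

The market quality of cured tobacco leaves — operationalized as price per kg
dry weight, z-score standardized — depends on seven measurable leaf
variables: blue mold severity (BMS, % leaf damage from *Peronospora
tabacina*), chlorophyll index (Chl), and total nitrogen (N), sugar (S),
nicotine (Nt), chloride (Cl) and potassium (K) contents (% w/w).  The
disease effect is large, negative and saturating, which puts the problem
outside the comfort zone of linear regression.  This package provides, for
analysts of such agronomic quality data:

- a **single-hidden-layer perceptron** with tansig activations
  (`tansig(u) = 2/(1+e^{-2u}) - 1`), whose forward pass for input `x` is

  `ŷ = tansig( Σ_j ωo_j · tansig( Σ_i ωh_ij x_i + β_j ) + β_out )`

- a **real-coded genetic algorithm** that trains the flattened weight/bias
  vector by minimizing training RMSE: roulette-wheel selection (slice ∝
  1/RMSE), single-point crossover (rate 0.85), per-gene uniform-reset
  mutation (rate 0.01), population 50, 500 generations, elitism, and an
  optional BFGS polish of the best chromosome (exact backprop gradient);

- the five standard **regression baselines** — multiple linear (MLR),
  bidirectional p-value stepwise (SR), ordinary least squares (OLSR),
  NIPALS PLS1 (PLSR), and principal component regression (PCR) — evaluated
  under the identical protocol;

- **repeated five-fold cross-validation** (10 repeats) reporting R², RMSE
  and MAPE on training and testing portions, with all preprocessing
  (Box-Cox, range scaling) fitted on training folds only;

- **VSE/VSR sensitivity analysis**: the variable sensitivity error is the
  model RMSE with one input neutralized (mean-imputed by default); dividing
  by the full-model RMSE gives the variable sensitivity ratio, min-max
  rescaled to [0, 1] so the most influential variable scores exactly 1;

- a **synthetic tobacco-like data generator** (4 cultivars × 2 seasons,
  100 plants per cultivar) reproducing the statistical shape of such field
  studies, so the whole pipeline is testable end to end.

## Worked example

```r
library(leafqnn)

# Generate a field-shaped dataset: 4 cultivars x 2 seasons, 100 plants each
d <- generate_tobacco_like(generator_config(seed = 1))
head(round(d[, 1:8], 2), 3)
#>     bms   chl    n    s    nt   cl    k quality
#> 1 19.67 39.70 2.04 6.04 21.02 2.55 2.42   -1.36
#> 2 42.87 36.19 3.11 7.09 26.04 2.59 1.64   -1.52
#> 3 23.72 37.17 2.21 5.48 24.22 2.64 1.94   -1.09

X <- predictor_matrix(d)

# Train the perceptron (5 hidden tansig neurons) with the GA + BFGS polish
model <- fit_mlp_ga(X, d$quality, n_hidden = 5,
                    config = ga_config(generations = 150,
                                       local_refinement = TRUE, seed = 1))

# Compare with multiple linear regression under 5-fold x 10 CV
plan <- make_fold_plan(nrow(X), k = 5, repeats = 10, seed = 1)
cv_mlp <- cross_validate(spec_mlp_ga(5, ga_config(generations = 150,
                                                  local_refinement = TRUE,
                                                  seed = 1)),
                         X, d$quality, plan)
cv_mlr <- cross_validate(spec_baseline("mlr"), X, d$quality, plan)
rbind(cv_mlp$testing, cv_mlr$testing)
#>      model  subset        r2      rmse     mape
#> 1 MLPNN-GA testing 0.8841217 0.3554149 89.49966
#> 2      MLR testing 0.8708692 0.3755041 81.02160

# Rank the inputs by ablation sensitivity
build_sensitivity_report(model, X, d$quality)
#> <sensitivity report> baseline RMSE 0.3051, policy 'mean'
#>   variable    vse vsr_raw vsr_rescaled
#> 1      bms 0.7786   2.552      1.00000
#> 2      chl 0.4085   1.339      0.18177
#> 3       cl 0.3839   1.258      0.12731
#> 4        n 0.3744   1.227      0.10638
#> 5        s 0.3550   1.164      0.06351
#> 6       nt 0.3531   1.157      0.05924
#> 7        k 0.3263   1.069      0.00000
```

Reading the output: the perceptron generalizes better than the linear fit
(testing R² 0.884 vs 0.871) because the blue-mold effect saturates; ablating
BMS inflates the model error 2.55-fold (VSE 0.78 vs baseline RMSE 0.31), far
more than any chemical variable, so its rescaled VSR is 1 — blue mold
dominates leaf quality.  MAPE values are large on this scale because
z-scored responses sit near zero; they are comparable across models, not
across response scales.

A full run — all six model families, per-cultivar and pooled subsets, both
report tables, convergence traces and a reproducibility manifest — is one
call (`run_pipeline(pipeline_config(seed = 1))`), or from a shell:

```sh
Rscript inst/cli/leafq.R run --outdir out --seed 1
```

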