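---
title: "Methods: GA-trained perceptron regression for leaf quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-trained perceptron regression for leaf quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, protocols, numerical choices and known
limitations of leafqnn, in the spirit of a methods section: everything a
user needs to judge what the package computes and why the defaults are what
they are.  No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## The regression problem

Rows are plants/plots; the seven predictors are blue mold severity (BMS, %
of leaf area damaged), chlorophyll index (Chl, unitless meter reading), and
nitrogen, sugar, nicotine, chloride and potassium contents (% w/w).  The
response is leaf quality: market price per kg dry weight, z-score
standardized (`price_to_quality()` / `quality_to_price()` map between the
scales; the default price mean and sd are 1579996.5 and 452320.3 Rials
kg⁻¹ DW).  Modeling on the z-score scale removes the currency unit; all
reported metrics are computed on this original response scale, never on the
network's internal scale.

## The perceptron and its training scale

The network has one hidden layer of `m` tansig neurons and a single tansig
output neuron.  For input `x`:

- hidden sums: `Sumh_j = Σ_i ωh_ij x_i + β_j`
- hidden outputs: `yh_j = tansig(Sumh_j)`, with
  `tansig(u) = 2/(1 + e^{-2u}) - 1`
- output: `ŷ = tansig(Σ_j ωo_j yh_j + β_out)`

`tansig` is identically `tanh`; the package implements the `2/(1+e^{-2u})-1`
form directly (the intermediate `exp` may overflow to `Inf`, which
propagates to the correct ±1 limit) and the test suite checks it against
the independent closed form `2·logistic(2u) − 1` on a grid.

Because the output neuron is bounded in (−1, 1), the response must be
range-scaled before fitting.  `fit_mlp_ga()` scales every predictor column
to [−1, 1] and the response to **[−0.9, 0.9]**; the 0.1 margin keeps
targets away from the saturating tails where gradients vanish and the GA
landscape flattens.  Predictions are mapped back through the inverse
scaling, so cross-validated metrics are always on the original scale, and
the test suite verifies that an affine change of response units leaves R²
unchanged to 1e-9.  Out-of-range values at prediction time are clamped to
the training range — the standard behavior for a bounded-output network,
warned about in the standalone scaler API and silent inside model
prediction where clamping single test rows is routine.

## Genetic-algorithm training

All weights and biases are flattened into one chromosome (hidden weights
column-major, hidden biases, output weights, output bias; length
`n·m + 2m + 1`, e.g. 46 genes for 7 inputs and 5 hidden neurons).  Fitness
is training RMSE — to be minimized.  Defaults follow the standard settings
for this family of models: population 50, crossover rate 0.85, mutation
rate 0.01, 500 generations.

Choices the bare description of a GA leaves open, fixed as follows:

- **Selection.** Roulette-wheel selection needs "fitter = larger slice",
  so slices are proportional to `1/(RMSE + 1e-12)`.  The epsilon only
  matters when a chromosome reaches exactly zero error, where it correctly
  hands that chromosome essentially the whole wheel.  Rank-based selection
  is available (`selection = "rank"`) for landscapes where a few very bad
  chromosomes would otherwise dominate the normalization.
- **Crossover.** Single-point on the flat gene vector (children conserve
  the parental gene multiset — a property test); arithmetic blend crossover
  is available as an option.
- **Mutation.** A rate of 0.01 is read as a **per-gene** reset probability
  (fresh uniform draw from the gene range), the standard interpretation of
  a real-coded mutation rate; the expected mutations per 46-gene chromosome
  are 0.46, and the test suite checks the realized count against
  Binomial(46, 0.01).  The alternative reading (exactly one allele per
  chromosome) would make the rate parameter meaningless.
- **Elitism.** One elite chromosome is copied unchanged each generation.
  Without it the best solution can be lost and the best-RMSE trace is not
  monotone; with it the trace is non-increasing (tested).  Set
  `elitism_count = 0` for the strictly operator-only loop.
- **Gene range.** [−1, 1], matching the scale of the inputs and targets.
  A wider range is rarely useful here because tansig saturates; the range
  is configurable, and in no experiment run for this package did the
  search stagnate in a way a wider range would fix — for that reason no
  automatic range widening is performed.
- **Local refinement.** `local_refinement = TRUE` appends a bounded BFGS
  polish (at most `refine_maxit = 200` iterations) of the best chromosome,
  using the exact backpropagation gradient of the mean squared error (the
  gradient is verified against numerical differentiation in the tests).
  A pure GA explores well but converges slowly near an optimum; the polish
  is the conventional hybrid remedy.  Results carry a `refined` flag so
  its use is always visible.

The hidden-neuron count is **not** encoded in the chromosome; it is
selected externally by `search_architecture()`, which cross-validates each
candidate count (default grid 1–10, covering the 4–6 range typical for
this problem size) and breaks ties toward fewer neurons.  Reproducibility:
every randomized stage takes a seed, and fold-level GA seeds are derived
deterministically from the configuration seed.

## Evaluation protocol

`make_fold_plan()` builds balanced random partitions: 5 folds, 10 repeats.
`cross_validate()` fits **all** preprocessing inside each training fold —
Box-Cox transforms of predictors when enabled, and the perceptron's
internal range scalers always — then reports R², RMSE and MAPE
on both portions, averaged over the 50 repeat×fold cells (mean of per-fold
metric values, not pooled residuals; the per-cell table is returned so
either aggregation can be recomputed).  A leakage audit in the test suite
corrupts the rows of one test fold and verifies the training-portion
metrics of that cell are bit-identical.

MAPE is undefined at zero actual values, which genuinely occur on a
z-scored response; rows with `|y| < 1e-8` are excluded from MAPE with a
logged count (`mape_excluded`).  MAPE on a z-score scale is dominated by
near-zero actuals and should only be compared across models on the same
response, never across response scales.

## Preprocessing

- **Box-Cox**: λ maximizes the profile log-likelihood, found by Brent's
  method on [−5, 5] (cross-checked against the MASS grid search in tests).
  Data containing zeros or negatives are shifted so the minimum maps to
  half a standard deviation above zero: a near-zero minimum (machine
  epsilon) would let `log` or negative powers explode on the low tail,
  which matters in practice because disease severity is exactly 0 on
  healthy plants.  Box-Cox is applied to **predictors only**; the response
  is already z-scored and symmetric by construction, and transforming it
  would change the scale on which errors are reported (a switch at the
  cross-validation layer could be added, but the default keeps the
  response untouched).
- **z-score**: sample standard deviation (n − 1), the convention of
  `stats::sd`; fixed and documented because the two conventions differ
  detectably at small n.
- **PCA outlier screen**: Hotelling's T² on the principal components
  covering ≥95% of variance of the standardized predictors, flagged above
  the `(1−α)` quantile of `k(n−1)/(n−k)·F(k, n−k)` with α = 0.01.  The
  screen is advisory (the pipeline reports the flag count in its
  manifest); on clean generated data it flags ~1% of multivariate-normal
  rows and none of the generator's truncated profiles.

## The synthetic-data generator

No field dataset ships with the package; `generate_tobacco_like()` emulates
the *statistical shape* such a study provides:

- 4 cultivars × 2 seasons, 100 rows per cultivar (400 pooled), matching
  the dimensions under which the analysis protocol is defined;
- predictors drawn from truncated normal profiles whose means shift by
  cultivar and season (mean shifts only — no interactions), anchored on
  reported field contrasts (highest blue mold in Bergerac, ~22.8% and
  ~35.5% across seasons; highest chlorophyll and sugar in Bell; highest
  nicotine and potassium in Burly; lowest nicotine in Basma) and truncated
  to plausible ranges (BMS 0–60%, Chl 25–50, N 1–4, S 0–15, Nt 0–35,
  Cl 0–4, K 1–4% w/w);
- a quality response built on the z-score scale as
  `bms_effect · driver(BMS) + Σ minor_j · z(chem_j) + ε`, standardized to
  unit variance before noise.  The blue-mold driver is
  `(1−w)·z + w·tanh(2z)` with `w = nonlin_scale = 0.75`: a **strongly
  saturating** disease-damage response (quality loss levels off at high
  severity), strictly monotone so that in the noiseless single-driver case
  the rank correlation between quality and BMS is exactly −1.  An earlier,
  gentler form (half linear, half `tanh(1.5z)`) turned out to be almost
  collinear with a straight line, i.e. not meaningfully nonlinear; the
  steeper mix was fixed once as the generator's defining condition.
- defaults `bms_effect = −1` (strictly the largest effect, the structure
  the VSE/VSR analysis assumes) and `noise_sd = 0.3` on the z-score scale,
  a realistic field-noise level that caps the achievable R² near 0.92.

What the generator does **not** emulate: measurement error structure of
real assays, cultivar×season interactions, spatial/plot correlation,
heteroscedastic pricing, or the true functional form linking chemistry to
price — none of which are published for this system.  Tests passing on
generated data therefore validate the machinery and its structural claims
(dominant-variable recovery, nonlinear-vs-linear ordering), not field
performance.

`generate_teacher_mlp()` provides the complementary fixture: data whose
generating process *is* a known perceptron, so fit recovery has an exact
target (the teacher explains its own noiseless data with R² = 1, and a
correctly trained model should approach that on held-out rows).

## Baselines

MLR and OLSR are the same least-squares estimator — they are
mathematically identical for a fixed design matrix; both labels are kept
so reports mirror the conventional five-family comparison, and any
difference between them in published tables can only reflect differing
preprocessing or fold draws.  Stepwise uses classical bidirectional
p-value selection (enter < 0.05, remove > 0.10) on partial-F statistics;
note the family-wise consequence that with six inert candidates the
all-and-only-signal support is recovered in about `0.95⁶ ≈ 74%` of
datasets, not 95% — the per-variable, not family-wise, rate is what the
thresholds control.  PLSR is a NIPALS PLS1 on standardized predictors
(cross-checked against mixOmics), PCR regresses on leading principal
components; both select their component count by inner cross-validation
when asked (`n_components = "auto"`), and both collapse to the MLR fit at
the full component count — the four-way equivalence
`MLR ≡ OLSR ≡ PCR(7) ≡ PLSR(7)` is asserted across random datasets in the
acceptance tests.

## Sensitivity analysis

"Removed or unavailable" is operationalized as **mean imputation without
retraining** (default): the column is replaced by its training mean, the
model is not refit, and the RMSE under ablation is the VSE.  Permutation
(`neutralize = "permute"`) and full retraining without the variable
(`neutralize = "retrain"`) are provided; on dominant-driver data all three
agree on the top variable (tested).  VSR = VSE / baseline RMSE; min-max
rescaling forces the most sensitive variable to exactly 1 and the least to
exactly 0, matching the convention of reporting both extremes.  If the
model is degenerate (baseline RMSE 0) the ratio is undefined and the
package says so rather than inventing a value; if all ratios tie, all
variables rescale to 1 with a warning.  By default the report is computed
on all rows (train + test), the usual convention for a post-selection
importance analysis.

## Problem sizes in tests and experiments

The shipped experiments are sized for a single CPU: the teacher-recovery
experiment uses n = 100, an 80/20 split, hidden grid 3–7 selected by
five-fold (one repeat) cross-validation inside the training portion, and
the full GA budget (50 × 500) with the BFGS polish, median over 5 seeds;
the headline perceptron-vs-linear comparison uses 400-row datasets and a
150-generation GA; the demo pipeline runs all six families at 100
generations under the full 5×10 CV.  These are the package's chosen
experiment definitions — enlarging them changes runtime, not the
methodology.

## Known limitations

- Pure GA training without the polish rarely reaches the near-perfect fits
  a gradient method attains on realizable data; the polish is therefore on
  in every shipped experiment and flagged in results.
- Per-cultivar subsets (100 rows) give the 46-parameter network little
  data; on noisy subsets linear baselines can win there, and the package
  reports whatever the comparison yields rather than privileging the
  network.
- The stepwise family-wise selection behavior above is inherent to
  p-value stepwise regression, not a defect of the implementation.
- MAPE on z-scored responses is fragile by construction; prefer R²/RMSE.
- The generator's cultivar profiles are anchored on a handful of published
  contrasts; they are plausible, not estimated from data.
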