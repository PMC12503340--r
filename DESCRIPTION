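Package: leafqnn
Title: Leaf Quality Prediction with a GA-Trained Multilayer Perceptron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts crop leaf quality (z-scored market price per kg dry
    weight) from seven leaf and disease predictors -- blue mold severity,
    chlorophyll index, and nitrogen, sugar, nicotine, chloride and potassium
    contents -- using a single-hidden-layer tansig multilayer perceptron whose
    weights and biases are trained by a real-coded genetic algorithm (roulette
    selection, single-point crossover, uniform mutation, elitism) with RMSE as
    the fitness function.  Benchmarks the network against five linear
    regression families (multiple linear, stepwise, ordinary least squares,
    partial least squares, principal component regression) under a repeated
    five-fold cross-validation protocol, and ranks input variables by the
    variable sensitivity error / variable sensitivity ratio (VSE/VSR)
    ablation procedure.  Includes a synthetic tobacco-like data generator so
    the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
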