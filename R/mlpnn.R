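#' Single-hidden-layer perceptron architecture
#'
#' Describes the network topology used throughout the package: `n_inputs`
#' input neurons, one hidden layer of `n_hidden` tansig neurons, and a single
#' tansig output neuron.  Because both layers use the tansig activation the
#' network output is always strictly inside (-1, 1); the training pipeline
#' therefore range-scales the response into a sub-interval of (-1, 1) before
#' fitting (see [fit_mlp_ga()]).
#'
#' @param n_inputs Number of input neurons (predictor variables), >= 1.
#' @param n_hidden Number of hidden neurons, >= 1.
#' @return An object of class `mlp_architecture`.
#' @seealso [mlp_parameters()], [mlp_forward()]
#' @export
#' @examples
#' arch <- mlp_architecture(7, 5)
#' n_genes(arch) # 7*5 + 5 + 5 + 1 = 46
mlp_architecture <- function(n_inputs, n_hidden) {
  n_inputs <- check_count(n_inputs, "n_inputs")
  n_hidden <- check_count(n_hidden, "n_hidden")
  structure(
    list(n_inputs = n_inputs, n_hidden = n_hidden, n_outputs = 1L,
         activation = "tansig"),
    class = "mlp_architecture"
  )
}

#' Chromosome length of an architecture
#'
#' Number of free parameters (= genes in the GA encoding): hidden weights,
#' hidden biases, output weights, output bias.
#'
#' @param arch An [mlp_architecture()].
#' @return Integer gene-vector length.
#' @export
n_genes <- function(arch) {
  stopifnot(inherits(arch, "mlp_architecture"))
  arch$n_inputs * arch$n_hidden + 2L * arch$n_hidden + 1L
}

#' Weights and biases of the perceptron
#'
#' @param hidden_weights `n_inputs x n_hidden` matrix; entry (i, j) connects
#'   input neuron i to hidden neuron j.
#' @param hidden_biases Length-`n_hidden` vector of hidden-neuron biases.
#' @param output_weights Length-`n_hidden` vector connecting hidden neurons to
#'   the single output neuron.
#' @param output_bias Scalar bias of the output neuron.
#' @return An object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(hidden_weights, hidden_biases, output_weights,
                           output_bias) {
  if (!is.matrix(hidden_weights) || !is.numeric(hidden_weights)) {
    stop("'hidden_weights' must be a numeric matrix", call. = FALSE)
  }
  nh <- ncol(hidden_weights)
  if (length(hidden_biases) != nh || length(output_weights) != nh ||
      length(output_bias) != 1L) {
    stop("parameter shapes are inconsistent with the hidden-weight matrix",
         call. = FALSE)
  }
  vals <- c(hidden_weights, hidden_biases, output_weights, output_bias)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  structure(
    list(hidden_weights = hidden_weights,
         hidden_biases = as.numeric(hidden_biases),
         output_weights = as.numeric(output_weights),
         output_bias = as.numeric(output_bias)),
    class = "mlp_parameters"
  )
}

mlp_arch_of <- function(params) {
  mlp_architecture(nrow(params$hidden_weights), ncol(params$hidden_weights))
}

#' Tansig activation
#'
#' The hyperbolic-tangent-shaped sigmoid `2 / (1 + exp(-2u)) - 1`, an odd
#' function with range (-1, 1).  Saturates to +/-1 for large `|u|` without
#' overflow (the intermediate `exp` may reach `Inf`, which propagates to the
#' correct limit).
#'
#' @param u Numeric vector or matrix.
#' @return Activation values, same shape as `u`.
#' @export
#' @examples
#' tansig(0)    # 0
#' tansig(0.5)  # ~0.462117
tansig <- function(u) 2 / (1 + exp(-2 * u)) - 1

#' Hidden-layer summation
#'
#' Pre-activation sums of the hidden layer for a single input vector:
#' `Sumh_j = sum_i w_ij x_i + b_j`.
#'
#' @param x Numeric vector of length `n_inputs`.
#' @param params An [mlp_parameters()] object.
#' @return Numeric vector of length `n_hidden`.
#' @export
hidden_sums <- function(x, params) {
  stopifnot(inherits(params, "mlp_parameters"))
  if (length(x) != nrow(params$hidden_weights) || anyNA(x) ||
      any(!is.finite(x))) {
    stop("'x' must be a finite vector of length n_inputs", call. = FALSE)
  }
  drop(crossprod(params$hidden_weights, x)) + params$hidden_biases
}

#' Forward pass of the perceptron
#'
#' Computes `tansig( sum_j w_out_j * tansig(Sumh_j) + b_out )` for one input
#' vector or, vectorized, for every row of an input matrix.  The result is
#' strictly inside (-1, 1).
#'
#' @param params An [mlp_parameters()] object.
#' @param x Numeric vector of length `n_inputs`, or a matrix with `n_inputs`
#'   columns (one prediction per row).
#' @return A scalar (vector input) or a numeric vector (matrix input).
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_parameters"))
  single <- !is.matrix(x)
  X <- if (single) matrix(x, nrow = 1L) else x
  if (ncol(X) != nrow(params$hidden_weights)) {
    stop("input has the wrong number of columns for this architecture",
         call. = FALSE)
  }
  H <- tansig(X %*% params$hidden_weights +
                rep(params$hidden_biases, each = nrow(X)))
  out <- tansig(drop(H %*% params$output_weights) + params$output_bias)
  if (single) out[[1L]] else out
}

#' Flatten parameters to a gene vector
#'
#' Fixed layout: hidden weights column-major (all weights into hidden neuron 1
#' first), then hidden biases, output weights, output bias.  The inverse is
#' [mlp_decode()]; `mlp_decode(mlp_encode(p), arch)` is an exact round trip.
#'
#' @param params An [mlp_parameters()] object.
#' @return Numeric vector of length [n_genes()].
#' @export
mlp_encode <- function(params) {
  stopifnot(inherits(params, "mlp_parameters"))
  c(as.vector(params$hidden_weights), params$hidden_biases,
    params$output_weights, params$output_bias)
}

#' @rdname mlp_encode
#' @param genes Numeric vector of length [n_genes()]`(arch)`.
#' @param arch An [mlp_architecture()].
#' @export
mlp_decode <- function(genes, arch) {
  stopifnot(inherits(arch, "mlp_architecture"))
  L <- n_genes(arch)
  if (length(genes) != L) {
    stop(sprintf("gene vector has length %d; architecture requires %d",
                 length(genes), L), call. = FALSE)
  }
  ni <- arch$n_inputs
  nh <- arch$n_hidden
  mlp_parameters(
    hidden_weights = matrix(genes[seq_len(ni * nh)], ni, nh),
    hidden_biases  = genes[ni * nh + seq_len(nh)],
    output_weights = genes[ni * nh + nh + seq_len(nh)],
    output_bias    = genes[ni * nh + 2L * nh + 1L]
  )
}

# Fast forward pass on raw genes; the GA inner loop avoids building
# mlp_parameters objects.
mlp_forward_genes <- function(genes, ni, nh, X) {
  W <- matrix(genes[seq_len(ni * nh)], ni, nh)
  b1 <- genes[ni * nh + seq_len(nh)]
  w2 <- genes[ni * nh + nh + seq_len(nh)]
  b2 <- genes[ni * nh + 2L * nh + 1L]
  H <- tansig(X %*% W + rep(b1, each = nrow(X)))
  tansig(drop(H %*% w2) + b2)
}

# Gradient of the mean squared error wrt the flat gene vector (backprop for
# the one-hidden-layer tansig net); used by the optional local refinement.
mlp_mse_grad <- function(genes, ni, nh, X, y) {
  n <- nrow(X)
  W <- matrix(genes[seq_len(ni * nh)], ni, nh)
  b1 <- genes[ni * nh + seq_len(nh)]
  w2 <- genes[ni * nh + nh + seq_len(nh)]
  b2 <- genes[ni * nh + 2L * nh + 1L]
  H <- tansig(X %*% W + rep(b1, each = n))
  so <- drop(H %*% w2) + b2
  pred <- tansig(so)
  dso <- (2 / n) * (pred - y) * (1 - pred^2)
  gw2 <- drop(crossprod(H, dso))
  gb2 <- sum(dso)
  dS1 <- (dso %o% w2) * (1 - H^2)
  gW <- crossprod(X, dS1)
  c(as.vector(gW), colSums(dS1), gw2, gb2)
}

#' Serialize / deserialize perceptron parameters
#'
#' Parameters are stored as JSON: architecture, the flat gene vector in the
#' [mlp_encode()] layout, and a layout version tag.
#'
#' @param params An [mlp_parameters()] object.
#' @param path File path.
#' @return `write_mlp_json` returns `path` invisibly; `read_mlp_json` returns
#'   an [mlp_parameters()] object.
#' @export
write_mlp_json <- function(params, path) {
  arch <- mlp_arch_of(params)
  obj <- list(layout = "mlp-flat-v1",
              n_inputs = arch$n_inputs, n_hidden = arch$n_hidden,
              genes = mlp_encode(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$layout, "mlp-flat-v1")) {
    stop("unrecognized parameter layout tag: ", obj$layout, call. = FALSE)
  }
  mlp_decode(as.numeric(obj$genes),
             mlp_architecture(obj$n_inputs, obj$n_hidden))
}
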