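`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_config(field, sprintf("must be a single finite number in [%g, %g]",
                               min, max))
  }
  as.numeric(x)
}

check_matrix <- function(X, field = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("'%s' must be a numeric matrix", field), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("'%s' contains missing or non-finite values", field),
         call. = FALSE)
  }
  X
}
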