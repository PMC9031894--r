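# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# Probabilities are clamped before logs so cross-entropy never returns -Inf.
PROB_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid("non-finite values in %s", what)
  invisible(x)
}

check_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("%s must be a single positive number", what)
  invisible(x)
}
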