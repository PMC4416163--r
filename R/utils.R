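# Internal helpers: classed conditions and seeded evaluation.

stop_golsa <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "golsa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parse  <- function(msg, ...) stop_golsa("golsa_parse_error", msg, ...)
stop_config <- function(msg, ...) stop_golsa("golsa_config_error", msg, ...)
stop_input  <- function(msg, ...) stop_golsa("golsa_input_error", msg, ...)
stop_numeric <- function(msg, ...) stop_golsa("golsa_numeric_error", msg, ...)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic generators in the package route through this so they are
# pure functions of their (spec, seed) arguments.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
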