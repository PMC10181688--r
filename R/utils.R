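# Internal helpers: classed error conditions and seed scoping.

abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cdvar_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_validation <- function(message) abort(message, "cdvar_validation_error")
abort_data       <- function(message) abort(message, "cdvar_data_error")
abort_numerical  <- function(message) abort(message, "cdvar_numerical_error")

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    abort_validation(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s; got %s",
      name, if (strict) "(" else "[", format(lower), format(upper),
      if (strict) ")" else "]",
      paste(utils::head(format(x), 3), collapse = ", ")
    ))
  }
  invisible(x)
}
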