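#' @importFrom Rcpp sourceCpp
#' @useDynLib bodyscan, .registration = TRUE
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_bodyscan <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(class, "bodyscan_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

warn_bodyscan <- function(class, message) {
  warning(structure(
    class = c(class, "bodyscan_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
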