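#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (!all(is.finite(x)))
    stopf("%s contains non-finite values", what)
  invisible(x)
}
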