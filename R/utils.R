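#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL leaves the RNG stream untouched (draws consume the global
# stream), which callers use to chain sub-simulations off one master seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_arg <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("'%s' must be a finite numeric scalar", name))
  if (if (strict_lower) x <= lower else x < lower)
    stop_arg(sprintf("'%s' must be %s %g", name,
                     if (strict_lower) ">" else ">=", lower))
  if (if (strict_upper) x >= upper else x > upper)
    stop_arg(sprintf("'%s' must be %s %g", name,
                     if (strict_upper) "<" else "<=", upper))
  invisible(x)
}
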