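# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf,
                               lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  ok <- if (lo_open) x > lo else x >= lo
  ok <- ok && if (hi_open) x < hi else x <= hi
  if (!ok) {
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}
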