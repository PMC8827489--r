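# internal numerical helpers

# log(1 - exp(-a)) for a > 0, stable near both ends
log1mexp <- function(a) {
  ifelse(a < log(2), log(-expm1(-a)), log1p(-exp(-a)))
}

# validate a strictly positive finite scalar, naming the offender
check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop(sprintf("parameter '%s' must be a positive finite number (got %s)",
                 name, paste(format(value), collapse = ", ")), call. = FALSE)
  invisible(value)
}

check_probability <- function(p, name, allow_one = TRUE) {
  bad <- !is.finite(p) | p < 0 | (if (allow_one) p > 1 else p >= 1)
  if (any(bad))
    stop(sprintf("'%s' must lie in [0, %s]", name, if (allow_one) "1" else "1)"),
         call. = FALSE)
  invisible(p)
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
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

# deterministic per-replicate seed below 2^31
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(r)) %% 2147483629)
}

# generalized binomial coefficient choose(y, m) for real y, integer m >= 0,
# via the falling-factorial product (exact sign handling, small m only)
gchoose <- function(y, m) {
  if (m < 0) stop("m must be a nonnegative integer")
  if (m == 0) return(1)
  prod(y - seq_len(m) + 1) / factorial(m)
}
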