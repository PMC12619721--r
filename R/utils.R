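# internal helpers shared across modules

# evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream"
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (abs(seed) >= 2^31) stop("seed must fit in a 32-bit integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# "round" in the classical half-up sense; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu)^2) / (n - 1L))
}
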