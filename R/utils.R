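# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Numerically stable softplus and its inverse; keeps feature weights >= 0.
softplus <- function(r) pmax(r, 0) + log1p(exp(-abs(r)))

softplus_inv <- function(s) {
  stopifnot(all(s > 0))
  s + log(-expm1(-s))
}

sigmoid <- function(r) stats::plogis(r)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
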