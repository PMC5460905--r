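# Internal helpers shared across modules.

# Evaluate expr with a local RNG stream: the global .Random.seed is left
# untouched, and the same (seed, expr) pair always sees the same stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit integer hash of a non-negative integer vector
# (djb2-style, modulo the Mersenne prime 2^31 - 1). All arithmetic stays
# below 2^53 so the result is exact in doubles on every platform.
hashInts <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + as.double(x)) %% 2147483647
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
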