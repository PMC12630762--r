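# internal helpers shared across modules

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
# Every stochastic operation in the package funnels its draws through this so
# that a given seed reproduces byte-identical output regardless of what the
# caller's RNG was doing.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds from one master seed (keeps sub-stage
# determinism independent of how many draws earlier stages consumed)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

vec3 <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  x
}

norm3 <- function(x) sqrt(sum(x^2))

unit3 <- function(x) {
  n <- norm3(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a
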