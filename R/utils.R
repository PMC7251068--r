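# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so seeded helpers compose without side
# effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed. Keeps results
# below 2^31 so the value is a valid R integer.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_symmetric_num <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Min-max rescale a vector to [0, 1]; errors on zero spread.
minmax01 <- function(x, what = "values") {
  rng <- range(x)
  if (diff(rng) == 0) stopf("cannot min-max scale %s with zero spread", what)
  (x - rng[1]) / (rng[2] - rng[1])
}
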