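# Seed the RNG for the calling function's lifetime, restoring any prior
# state on exit so seeded package functions never disturb the caller's
# random stream.
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(seed)
}

# Derive independent sub-seeds from one master seed, kept within 32-bit
# integer range. Used so pipeline stages can be re-run independently.
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) * 1103L + stream * 7919L + seq_len(n) * 104729L) %% 2147483647L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
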