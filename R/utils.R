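# Internal helpers shared across modules.

# Deterministic substream seeds: fold integer keys into a 31-bit seed with a
# multiplicative hash (exact in double precision), so that any subset of the
# simulation (a participant, a permutation) is reproducible from the master
# seed without consuming the global RNG stream sequentially.
substream_seed <- function(master, ...) {
  keys <- c(...)
  h <- (abs(as.numeric(master)) + 1) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) + 1) * 16807) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Map a time window in ms to sample indices on a grid; endpoints inclusive.
window_index <- function(times_ms, window_ms) {
  stopifnot(length(window_ms) == 2)
  idx <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (length(idx) == 0) {
    abort(sprintf("window [%g, %g] ms contains no samples", window_ms[1],
                  window_ms[2]), class = "spnlab_parameter_error")
  }
  idx
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite", name),
          class = "spnlab_parameter_error")
  }
  invisible(x)
}
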