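# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

stopifnot_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop(sprintf("'%s' must be a single finite number >= %s", name, lower))
  invisible(x)
}

# Half-open [lo, hi) window on a time axis, 0-based semantics on the sample
# grid: samples with lo <= t < hi.
window_index <- function(time_ms, window) {
  if (window[1] > window[2]) stop("window must be increasing")
  which(time_ms >= window[1] & time_ms < window[2])
}

rms <- function(x) sqrt(mean(x^2))
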