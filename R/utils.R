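# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Weighted column means/SDs without forming centered copies.
col_weighted_stats <- function(x, w) {
  sw <- sum(w)
  mu <- as.vector(crossprod(x, w)) / sw
  ssq <- as.vector(crossprod(x * x, w))
  list(mean = mu, sw = sw, ssq = ssq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
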