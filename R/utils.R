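# Internal helpers: seed scoping and numerically stable log-sum-exp.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream of sub-seeds derived from one master seed.
# Kept below 2^31 so they remain valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Row-wise log(sum(exp(m))) for an n x K matrix; tolerates -Inf entries.
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) {
    for (k in 2L:ncol(m)) mx <- pmax(mx, m[, k])
  }
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
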