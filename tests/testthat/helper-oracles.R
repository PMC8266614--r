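# Independent oracles used across the test files.  These re-derive the
# quantities from first principles and deliberately share no code with the
# package implementation.

# Naive truncated-mixture density: literal transcription of the closed form,
# scalar arithmetic, no vectorization tricks.
oracle_pdf <- function(t, w, tau, t_min, t_max) {
  z <- 0
  for (k in seq_along(w)) {
    z <- z + w[k] * (exp(-t_min / tau[k]) - exp(-t_max / tau[k]))
  }
  num <- 0
  for (k in seq_along(w)) {
    num <- num + w[k] / tau[k] * exp(-t / tau[k])
  }
  num / z
}

# Matching closed-form CDF of the truncated mixture.
oracle_cdf <- function(t, w, tau, t_min, t_max) {
  z <- 0
  num <- 0
  for (k in seq_along(w)) {
    z <- z + w[k] * (exp(-t_min / tau[k]) - exp(-t_max / tau[k]))
    num <- num + w[k] * (exp(-t_min / tau[k]) - exp(-t / tau[k]))
  }
  num / z
}

# Naive negative log-likelihood by scalar summation.
oracle_nll <- function(durations, w, tau, t_min, t_max) {
  s <- 0
  for (t in durations) s <- s - log(oracle_pdf(t, w, tau, t_min, t_max))
  s
}

# Dense-grid K=1 maximum-likelihood search over tau (multiplicative grid).
# The K=1 NLL has the closed form n log(tau) + sum(t)/tau + n log(Z(tau)).
oracle_grid_mle_k1 <- function(durations, t_min, t_max,
                               lo = 0.1, hi = 100, step = 1.001) {
  taus <- exp(seq(log(lo), log(hi), by = log(step)))
  n <- length(durations)
  st <- sum(durations)
  z <- exp(-t_min / taus) - exp(-t_max / taus)
  nll <- n * log(taus) + st / taus + n * log(z)
  taus[which.min(nll)]
}

# One-sample Kolmogorov-Smirnov distance against an arbitrary CDF.
ks_distance <- function(x, cdf_fun) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf_fun(x)
  max(abs(fx - seq_len(n) / n), abs(fx - (seq_len(n) - 1) / n))
}

# Two-state model of the full-length substrate with Hfq alone, and the
# standard recording window, used by several files.
two_state_model <- function() mixture_model(c(0.56, 0.44), c(2, 60))
standard_window <- function() obs_window(0.1, 180)
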