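#' Bootstrap standard errors for mixture-fit parameters
#'
#' Nonparametric bootstrap of the dwell-time dataset: each replicate
#' resamples n events with replacement (or whole molecules, for the block
#' variant), refits the truncated mixture warm-started from the base optimum
#' plus a few random restarts, and records the parameters after
#' ascending-lifetime sorting.  The reported sigma per parameter is the
#' standard deviation of the retained bootstrap values (equivalently the
#' sigma of a normal distribution fitted to them).
#'
#' @param data A [dwell_dataset()].
#' @param K Number of components; ignored when `base_fit` is supplied.
#' @param n_boot Number of bootstrap replicates (the study convention is
#'   1000; smaller values trade precision of sigma for speed).
#' @param seed Master seed; every replicate consumes a derived sub-seed.
#' @param base_fit Optional [fit_mixture()] result to warm-start from;
#'   computed internally when missing.
#' @param n_restarts Random restarts per replicate in addition to the warm
#'   start (default 3).
#' @param unit `"event"` resamples individual binding events (the default);
#'   `"molecule"` resamples whole molecules (block bootstrap) when the
#'   dataset carries molecule ids.
#' @param retain_samples Keep the matrix of per-replicate parameter values.
#' @return An object of class `bootstrap_summary`: `summary` (data frame
#'   with columns `parameter`, `estimate`, `sigma`), `n_boot`, `failures`,
#'   `valid` (FALSE when more than 10% of replicates failed to converge),
#'   `samples` (optional matrix), and the `base_fit`.  Parameters are named
#'   `a1..aK` (weights) and `tau1..tauK` (lifetimes), components in
#'   ascending-lifetime order.
#' @export
bootstrap_fit <- function(data, K = NULL, n_boot = 1000L, seed = 1L,
                          base_fit = NULL, n_restarts = 3L,
                          unit = c("event", "molecule"),
                          retain_samples = TRUE) {
  stopifnot(inherits(data, "dwell_dataset"))
  unit <- match.arg(unit)
  if (is.null(base_fit)) {
    if (is.null(K)) stop("supply K or a base_fit")
    base_fit <- fit_mixture(data, K, seed = seed)
  }
  K <- base_fit$K
  if (unit == "molecule" && is.null(data$molecule_id)) {
    stop("molecule-level bootstrap requires molecule ids on the dataset")
  }
  t_all <- data$durations
  n <- length(t_all)
  base_par <- pack_par(base_fit$model$weights, base_fit$model$lifetimes)
  seeds <- derive_seeds(seed, n_boot)

  samples <- matrix(NA_real_, nrow = n_boot, ncol = 2L * K,
                    dimnames = list(NULL, c(paste0("a", seq_len(K)),
                                            paste0("tau", seq_len(K)))))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    rep_data <- with_seed(seeds[b], {
      if (unit == "event") {
        idx <- sample.int(n, n, replace = TRUE)
      } else {
        ids <- unique(data$molecule_id)
        pick <- sample(ids, length(ids), replace = TRUE)
        idx <- unlist(lapply(pick, function(m) which(data$molecule_id == m)),
                      use.names = FALSE)
      }
      starts <- c(list(base_par),
                  if (n_restarts > 0L) {
                    make_starts(t_all[idx], K, n_restarts + 1L,
                                sample.int(.Machine$integer.max - 1L, 1L),
                                data$window$t_min, data$window$t_max)[-1L]
                  })
      list(t = t_all[idx], starts = starts)
    })
    eng <- fit_engine(rep_data$t, data$window, K, rep_data$starts)
    ok <- !is.null(eng$best) &&
      any(eng$diagnostics$convergence == 0, na.rm = TRUE)
    if (!ok) {
      failures <- failures + 1L
      next
    }
    p <- unpack_par(eng$best$par, K)
    ord <- order(p$lifetimes)
    samples[b, ] <- c(p$weights[ord] / sum(p$weights), p$lifetimes[ord])
  }
  kept <- samples[stats::complete.cases(samples), , drop = FALSE]
  sig <- apply(kept, 2L, stats::sd)
  est <- c(base_fit$model$weights, base_fit$model$lifetimes)
  structure(list(summary = data.frame(parameter = colnames(samples),
                                      estimate = est, sigma = sig,
                                      row.names = NULL),
                 n_boot = as.integer(n_boot),
                 failures = failures,
                 valid = failures <= 0.1 * n_boot,
                 samples = if (retain_samples) kept else NULL,
                 base_fit = base_fit,
                 seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap summary: %d replicates, %d failed%s\n", x$n_boot,
              x$failures, if (x$valid) "" else " [INVALID: >10% failures]"))
  print(transform(x$summary, estimate = signif(estimate, 6),
                  sigma = signif(sigma, 6)), row.names = FALSE)
  invisible(x)
}

#' Error propagation for the residual mixture amplitude
#'
#' In a three-component fit the third amplitude is the residual
#' `a3 = 1 - a1 - a2`; its uncertainty follows by propagation as
#' `sigma_a3 = sqrt(sigma_a1^2 + sigma_a2^2)` (treating the two bootstrap
#' sigmas as uncorrelated).  For correlated resamples the direct bootstrap
#' sigma of `a3` (available from [bootstrap_fit()] samples) can differ; both
#' are reported by the pipeline.
#'
#' @param sigma_a1,sigma_a2 Non-negative amplitude standard deviations.
#' @return `sqrt(sigma_a1^2 + sigma_a2^2)`.
#' @examples
#' propagate_residual_sigma(0.04, 0.05)
#' @export
propagate_residual_sigma <- function(sigma_a1, sigma_a2) {
  if (any(sigma_a1 < 0) || any(sigma_a2 < 0)) {
    stop("sigmas must be non-negative")
  }
  sqrt(sigma_a1^2 + sigma_a2^2)
}

#' Binomial standard deviation for histogram bars
#'
#' Error bars on dwell-time histograms follow the binomial standard
#' deviation `sqrt(N * P * (1 - P))`, where N is the number of events and
#' P the event probability in the bar.
#'
#' @param N Number of events (>= 0).
#' @param P Event probability in \[0, 1\].
#' @return `sqrt(N * P * (1 - P))` in event counts.
#' @examples
#' histogram_bar_sigma(100, 0.5)
#' @export
histogram_bar_sigma <- function(N, P) {
  if (any(N < 0)) stop("N must be non-negative")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  sqrt(N * P * (1 - P))
}

#' Compare a fitted parameter between two conditions
#'
#' Two-tailed unpaired test of `estimate_a` versus `estimate_b` given their
#' bootstrap standard deviations: the statistic is
#' `(A - B) / sqrt(sigma_A^2 + sigma_B^2)`.  Under the default `"normal"`
#' policy the bootstrap sigma is treated as the estimator's standard error
#' and the statistic is referred to the standard normal; the `"welch"`
#' policy refers it to a t distribution with user-supplied degrees of
#' freedom (for parity with replicate-based t-tests).
#'
#' @param estimate_a,estimate_b Point estimates in the two conditions.
#' @param sigma_a,sigma_b Their standard errors (bootstrap sigmas), >= 0.
#' @param parameter Parameter name (for reporting).
#' @param labels Length-2 character vector of condition labels.
#' @param df_policy `"normal"` (default) or `"welch"`.
#' @param df Degrees of freedom, required for the `"welch"` policy.
#' @param alpha Significance level for the flag (default 0.05).
#' @return An object of class `comparison_result` with the difference, the
#'   test statistic, the two-tailed p value, and a significance flag; a
#'   `degenerate` flag marks the zero-sigma branch.
#' @examples
#' compare_conditions(0.44, 0.05, 0.70, 0.04)
#' @export
compare_conditions <- function(estimate_a, sigma_a, estimate_b, sigma_b,
                               parameter = "parameter",
                               labels = c("A", "B"),
                               df_policy = c("normal", "welch"), df = NULL,
                               alpha = 0.05) {
  df_policy <- match.arg(df_policy)
  if (sigma_a < 0 || sigma_b < 0) stop("sigmas must be non-negative")
  diff <- estimate_a - estimate_b
  se <- sqrt(sigma_a^2 + sigma_b^2)
  degenerate <- FALSE
  if (se == 0) {
    degenerate <- TRUE
    if (diff == 0) {
      statistic <- 0
      p <- 1
    } else {
      statistic <- sign(diff) * Inf
      p <- 0
    }
  } else if (diff == 0) {
    statistic <- 0
    p <- 1
  } else {
    statistic <- diff / se
    p <- switch(df_policy,
      normal = 2 * stats::pnorm(-abs(statistic)),
      welch = {
        if (is.null(df)) stop("the 'welch' policy requires 'df'")
        2 * stats::pt(-abs(statistic), df = df)
      })
  }
  structure(list(parameter = parameter, labels = labels,
                 estimate_a = estimate_a, estimate_b = estimate_b,
                 difference = diff, statistic = statistic, p_value = p,
                 significant = p < alpha, alpha = alpha,
                 df_policy = df_policy, df = df, degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g vs %s = %.4g | z = %.4g | two-tailed p = %.4g%s\n",
              x$parameter, x$labels[1L], x$estimate_a, x$labels[2L],
              x$estimate_b, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
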