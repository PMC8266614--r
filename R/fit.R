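# Maximum-likelihood fitting of truncated exponential mixtures.
#
# Parameterization used by the optimizer: for K components the parameter
# vector is c(alpha_2..alpha_K, log tau_1..log tau_K) where the weights are
# softmax(c(0, alpha)).  This keeps the weights on the simplex and the
# lifetimes positive without constraints.

unpack_par <- function(par, K) {
  if (K == 1L) {
    list(weights = 1, lifetimes = exp(par))
  } else {
    z <- c(0, par[seq_len(K - 1L)])
    z <- z - max(z)
    w <- exp(z) / sum(exp(z))
    list(weights = w, lifetimes = exp(par[K:(2L * K - 1L)]))
  }
}

pack_par <- function(weights, lifetimes) {
  K <- length(weights)
  w <- pmax(weights, 1e-12)
  if (K == 1L) log(lifetimes) else c(log(w[-1L] / w[1L]), log(lifetimes))
}

mixture_nll_par <- function(par, t, t_min, t_max, K) {
  p <- unpack_par(par, K)
  if (any(!is.finite(p$lifetimes)) || any(p$lifetimes <= 0) ||
      any(!is.finite(p$weights))) {
    return(1e12)
  }
  nll <- -sum(log_truncated_pdf(t, p$weights, p$lifetimes, t_min, t_max))
  if (!is.finite(nll)) 1e12 else nll
}

# Deterministic multi-start initial values.  Start 1 is data-driven
# (spread quantiles of the observed dwells, equal weights); the remaining
# starts draw lifetimes log-uniformly over the initialization range and
# weights uniformly on the simplex, from a stream derived from `seed`.
make_starts <- function(durations, K, n_starts, seed, t_min, t_max) {
  upper <- if (is.finite(t_max)) t_max else max(durations) * 10
  q <- stats::quantile(durations, probs = (2 * seq_len(K) - 1) / (2 * K),
                       names = FALSE, type = 7)
  q <- pmin(pmax(q, t_min * 1.01), upper)
  starts <- list(pack_par(rep(1 / K, K), sort(q)))
  if (n_starts > 1L) {
    rng <- with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        tau <- exp(stats::runif(K, log(t_min), log(upper)))
        g <- stats::rexp(K)
        list(w = g / sum(g), tau = sort(tau))
      })
    })
    starts <- c(starts, lapply(rng, function(s) pack_par(s$w, s$tau)))
  }
  starts
}

# Core optimizer: minimizes the truncated-mixture NLL from each start,
# returns the best converged optimum (ties broken by lowest start index).
fit_engine <- function(durations, window, K, starts,
                       reltol = 1e-10, maxit = 2000L) {
  t_min <- window$t_min
  t_max <- window$t_max
  diag <- data.frame(start = seq_along(starts), nll = NA_real_,
                     convergence = NA_integer_)
  best <- NULL
  for (i in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], mixture_nll_par, t = durations,
                   t_min = t_min, t_max = t_max, K = K, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    diag$nll[i] <- opt$value
    diag$convergence[i] <- opt$convergence
    if (opt$value < 1e12 &&
        (is.null(best) || opt$value < best$value - 1e-12)) {
      best <- opt
      best$start <- i
    }
  }
  list(best = best, diagnostics = diag)
}

#' Fit a truncated K-exponential mixture to dwell times by maximum likelihood
#'
#' Maximizes the truncated-mixture likelihood (see [truncated_pdf()]) over
#' the un-binned dwell times, with the mixture weights simplex-constrained
#' through an unconstrained reparameterization and the lifetimes optimized
#' on the log scale.  Multiple deterministic, seed-derived starting points
#' guard against local optima; the best local optimum is returned with
#' lifetimes sorted ascending (weights permuted accordingly).
#'
#' @param data A [dwell_dataset()].
#' @param K Number of exponential components (1-4).
#' @param n_starts Number of optimizer starts (default 20).
#' @param seed Seed for the start-point stream.
#' @param guard Minimum events required per component (default 10; the fit
#'   refuses datasets with fewer than `guard * K` events).
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum optimizer iterations per start.
#' @return An object of class `fit_result` with elements `model`
#'   ([mixture_model()], lifetimes ascending), `window`, `log_likelihood`,
#'   `K`, `n_events`, `converged`, `n_starts_used`, `bic`,
#'   `identifiability_warning` (TRUE when two fitted lifetimes are within
#'   5% of each other) and `start_diagnostics`.
#' @examples
#' d <- simulate_dwells(mixture_model(1, 5), obs_window(0.1, 1e6),
#'                      sim_config(500, seed = 1))
#' fit_mixture(d, K = 1, n_starts = 5)
#' @export
fit_mixture <- function(data, K, n_starts = 20L, seed = 1L, guard = 10L,
                        reltol = 1e-10, maxit = 2000L) {
  stopifnot(inherits(data, "dwell_dataset"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  n <- length(data$durations)
  if (n < guard * K) {
    stop(sprintf("too few events for a K=%d fit: %d < %d (guard %d per component)",
                 K, n, guard * K, guard))
  }
  starts <- make_starts(data$durations, K, n_starts, seed,
                        data$window$t_min, data$window$t_max)
  eng <- fit_engine(data$durations, data$window, K, starts,
                    reltol = reltol, maxit = maxit)
  any_conv <- any(eng$diagnostics$convergence == 0, na.rm = TRUE)
  if (is.null(eng$best) || !any_conv) {
    stop("no optimizer start converged; per-start diagnostics:\n",
         paste(utils::capture.output(print(eng$diagnostics)), collapse = "\n"))
  }
  p <- unpack_par(eng$best$par, K)
  ord <- order(p$lifetimes)
  w <- p$weights[ord]
  model <- mixture_model(w / sum(w), p$lifetimes[ord])
  ident <- K > 1L && any(diff(model$lifetimes) / model$lifetimes[-K] < 0.05)
  if (ident) {
    warning("two fitted lifetimes are within 5% of each other; K may exceed ",
            "the number of resolvable components", call. = FALSE)
  }
  ll <- -eng$best$value
  structure(list(model = model,
                 window = data$window,
                 log_likelihood = ll,
                 K = K,
                 n_events = n,
                 converged = identical(eng$best$convergence, 0L) ||
                   eng$best$convergence == 0,
                 n_starts_used = length(starts),
                 bic = -2 * ll + (2L * K - 1L) * log(n),
                 identifiability_warning = ident,
                 condition = data$condition,
                 seed = seed,
                 best_start = eng$best$start,
                 start_diagnostics = eng$diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Truncated exponential-mixture fit (K = %d, n = %d events)\n",
              x$K, x$n_events))
  print(x$model)
  cat(sprintf("  log-likelihood %.4f | BIC %.2f | converged: %s\n",
              x$log_likelihood, x$bic, x$converged))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits every candidate K with [fit_mixture()] and returns the fit with the
#' lowest Bayesian information criterion, `BIC = -2 logL + (2K - 1) log n`.
#' Fit failures for individual K are recorded and do not abort the others.
#'
#' @param data A [dwell_dataset()].
#' @param candidate_Ks Candidate component counts, a subset of 1:4.
#' @param n_starts,seed,... Passed to [fit_mixture()].
#' @return The BIC-minimizing `fit_result`, with the full comparison table
#'   attached as `$bic_table` (columns `K`, `log_likelihood`, `n_par`,
#'   `bic`, `converged`, `error`).
#' @export
select_K <- function(data, candidate_Ks = 1:3, n_starts = 20L, seed = 1L, ...) {
  candidate_Ks <- as.integer(candidate_Ks)
  if (!all(candidate_Ks %in% 1:4)) {
    stop("candidate_Ks must be a subset of 1:4")
  }
  fits <- vector("list", length(candidate_Ks))
  tab <- data.frame(K = candidate_Ks, log_likelihood = NA_real_,
                    n_par = 2L * candidate_Ks - 1L, bic = NA_real_,
                    converged = NA, error = NA_character_)
  for (i in seq_along(candidate_Ks)) {
    f <- tryCatch(fit_mixture(data, candidate_Ks[i], n_starts = n_starts,
                              seed = seed, ...),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "fit_result")) {
      fits[[i]] <- f
      tab$log_likelihood[i] <- f$log_likelihood
      tab$bic[i] <- f$bic
      tab$converged[i] <- f$converged
    } else {
      tab$error[i] <- f
    }
  }
  ok <- which(!is.na(tab$bic))
  if (length(ok) == 0L) {
    stop("every candidate K failed to fit:\n",
         paste(sprintf("  K=%d: %s", tab$K, tab$error), collapse = "\n"))
  }
  best <- fits[[ok[which.min(tab$bic[ok])]]]
  best$bic_table <- tab
  best
}
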