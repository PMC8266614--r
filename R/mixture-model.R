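#' Exponential mixture model for dwell times
#'
#' A `mixture_model` describes a K-component exponential mixture of binding
#' lifetimes: component k has mixture weight (amplitude) `weights[k]` and
#' characteristic lifetime `lifetimes[k]` in seconds.  The amplitude of a
#' component is interpreted as the fraction of binding events that dissociate
#' with rate 1/lifetime.
#'
#' @param weights Numeric vector of mixture amplitudes; must lie in \[0, 1\]
#'   and sum to 1 (tolerance 1e-9).
#' @param lifetimes Numeric vector of characteristic lifetimes in seconds,
#'   strictly positive, same length as `weights`.
#'
#' @details
#' One to three components cover the regimes seen in single-molecule
#' co-localization studies of RNA/protein binding (transient, short-lived and
#' long-lived complexes).  Larger K is permitted but flagged with a warning,
#' as such fits are rarely identifiable from dwell-time data alone.
#'
#' @return An object of class `mixture_model` with elements `weights`,
#'   `lifetimes` and `K`.
#' @examples
#' m <- mixture_model(c(0.56, 0.44), c(2, 60))
#' @export
mixture_model <- function(weights, lifetimes) {
  weights <- as.numeric(weights)
  lifetimes <- as.numeric(lifetimes)
  if (length(weights) == 0L || length(weights) != length(lifetimes)) {
    stop("'weights' and 'lifetimes' must be non-empty and of equal length")
  }
  if (any(!is.finite(weights)) || any(!is.finite(lifetimes))) {
    stop("'weights' and 'lifetimes' must be finite")
  }
  if (any(weights < 0 | weights > 1)) {
    stop("every weight must lie in [0, 1]")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (tolerance 1e-9); got ", format(sum(weights)))
  }
  if (any(lifetimes <= 0)) {
    stop("every lifetime must be strictly positive")
  }
  K <- length(weights)
  if (K > 3L) {
    warning("more than three exponential components; such models are rarely ",
            "identifiable from dwell-time data", call. = FALSE)
  }
  structure(list(weights = weights, lifetimes = lifetimes, K = K),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Exponential mixture model (K = %d)\n", x$K))
  print(data.frame(component = seq_len(x$K),
                   weight = signif(x$weights, 6),
                   lifetime_s = signif(x$lifetimes, 6)), row.names = FALSE)
  invisible(x)
}

#' Observation window of a single-molecule recording
#'
#' The window is defined by the minimum resolvable time interval `t_min`
#' (events shorter than this cannot be detected) and the maximum observable
#' duration `t_max` (typically the recording length).  Dwell-time densities
#' are normalized over \[`t_min`, `t_max`\].
#'
#' @param t_min Minimum resolvable interval in seconds (default 0.1 s, one
#'   camera frame at the standard 0.1 s frame interval).
#' @param t_max Maximum observable duration in seconds (default 180 s, a
#'   3-minute movie); may be `Inf` for an effectively unbounded window.
#' @return An object of class `obs_window`.
#' @examples
#' w <- obs_window(0.1, 180)
#' @export
obs_window <- function(t_min = 0.1, t_max = 180) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || length(t_min) != 1L ||
      length(t_max) != 1L || is.na(t_min) || is.na(t_max)) {
    stop("'t_min' and 't_max' must be single numbers")
  }
  if (!(t_min > 0)) stop_field("t_min", "must be strictly positive")
  if (!(t_max > t_min)) stop_field("t_max", "must exceed t_min")
  structure(list(t_min = as.numeric(t_min), t_max = as.numeric(t_max)),
            class = "obs_window")
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf("Observation window: [%g, %g] s\n", x$t_min, x$t_max))
  invisible(x)
}

#' Dwell-time dataset
#'
#' Container for observed bound-interval durations (one per binding event)
#' under a single experimental condition, together with the observation
#' window they were recorded in.  Optionally carries per-event molecule
#' identifiers and event onset times (needed for rastergrams) and the counts
#' of raw events discarded by the window filters.
#'
#' @param durations Numeric vector of dwell times in seconds; every value
#'   must lie within the window.
#' @param window An [obs_window()].
#' @param condition Condition label (single string).
#' @param molecule_id Optional vector of per-event molecule identifiers.
#' @param start_s Optional numeric vector of event onset times in seconds.
#' @param n_discarded_short,n_discarded_long Counts of raw events removed
#'   because they were below `t_min` or extended beyond `t_max`.
#' @return An object of class `dwell_dataset`.
#' @export
dwell_dataset <- function(durations, window, condition = "unspecified",
                          molecule_id = NULL, start_s = NULL,
                          n_discarded_short = 0L, n_discarded_long = 0L) {
  stopifnot(inherits(window, "obs_window"))
  durations <- as.numeric(durations)
  if (any(!is.finite(durations))) stop("durations must be finite")
  tol <- 1e-9
  if (any(durations < window$t_min - tol)) {
    stop("durations below the minimum resolvable interval t_min")
  }
  if (any(durations > window$t_max + tol)) {
    stop("durations exceed the maximum observable duration t_max")
  }
  if (!is.null(molecule_id) && length(molecule_id) != length(durations)) {
    stop("'molecule_id' must match 'durations' in length")
  }
  if (!is.null(start_s) && length(start_s) != length(durations)) {
    stop("'start_s' must match 'durations' in length")
  }
  structure(list(durations = durations,
                 condition = as.character(condition)[1L],
                 window = window,
                 molecule_id = molecule_id,
                 start_s = if (is.null(start_s)) NULL else as.numeric(start_s),
                 n_discarded_short = as.integer(n_discarded_short),
                 n_discarded_long = as.integer(n_discarded_long)),
            class = "dwell_dataset")
}

#' @export
print.dwell_dataset <- function(x, ...) {
  cat(sprintf("Dwell-time dataset '%s': %d events in [%g, %g] s\n",
              x$condition, length(x$durations), x$window$t_min, x$window$t_max))
  cat(sprintf("  discarded: %d below t_min, %d beyond t_max\n",
              x$n_discarded_short, x$n_discarded_long))
  invisible(x)
}

#' Truncated mixture density of dwell times
#'
#' Probability density of the exponential mixture conditioned on the dwell
#' time falling inside the observation window:
#' \deqn{f(t) = \frac{\sum_k (w_k/\tau_k) e^{-t/\tau_k}}
#'   {\sum_k w_k (e^{-t_{min}/\tau_k} - e^{-t_{max}/\tau_k})}}
#' for \eqn{t \in [t_{min}, t_{max}]}.  The denominator renormalizes the
#' density over the window, so the fitted weights retain their meaning as
#' fractions of the underlying (untruncated) event population.
#'
#' @param t Numeric vector of dwell times in seconds, all inside the window.
#' @param model A [mixture_model()].
#' @param window An [obs_window()].
#' @return Density values (per second), strictly positive.
#' @examples
#' truncated_pdf(2, mixture_model(1, 2), obs_window(0.1, 1e9))
#' @export
truncated_pdf <- function(t, model, window) {
  stopifnot(inherits(model, "mixture_model"), inherits(window, "obs_window"))
  t <- as.numeric(t)
  tol <- 1e-12
  if (any(t < window$t_min - tol | t > window$t_max + tol)) {
    stop("dwell time outside the observation window [",
         window$t_min, ", ", window$t_max, "] s")
  }
  w <- model$weights
  tau <- model$lifetimes
  z <- window_mass(w, tau, window$t_min, window$t_max)
  dens <- as.vector(exp(-outer(t, 1 / tau)) %*% (w / tau)) / z
  dens
}

# Probability mass of the mixture inside [t_min, t_max]:
# sum_k w_k (exp(-t_min/tau_k) - exp(-t_max/tau_k)), computed via expm1 to
# avoid catastrophic cancellation when a lifetime far exceeds the window.
window_mass <- function(weights, lifetimes, t_min, t_max) {
  span <- if (is.finite(t_max)) {
    -expm1(-(t_max - t_min) / lifetimes)
  } else {
    rep(1, length(lifetimes))
  }
  sum(weights * exp(-t_min / lifetimes) * span)
}

#' Truncated mixture cumulative distribution of dwell times
#'
#' CDF companion of [truncated_pdf()]; returns
#' \eqn{P(T \le t \mid t_{min} \le T \le t_{max})}.
#'
#' @inheritParams truncated_pdf
#' @return Probabilities in \[0, 1\].
#' @export
truncated_cdf <- function(t, model, window) {
  stopifnot(inherits(model, "mixture_model"), inherits(window, "obs_window"))
  t <- as.numeric(t)
  tol <- 1e-12
  if (any(t < window$t_min - tol | t > window$t_max + tol)) {
    stop("dwell time outside the observation window [",
         window$t_min, ", ", window$t_max, "] s")
  }
  w <- model$weights
  tau <- model$lifetimes
  z <- window_mass(w, tau, window$t_min, window$t_max)
  s_min <- exp(-window$t_min / tau)
  # s_min - exp(-t/tau) = exp(-t_min/tau) * (1 - exp(-(t - t_min)/tau))
  part <- -expm1(-outer(t - window$t_min, 1 / tau))
  num <- as.vector(sweep(part, 2L, s_min, "*") %*% w)
  pmin(pmax(num / z, 0), 1)
}

# Log density on the unconstrained scale used by the optimizer; tolerates
# zero weights via log-sum-exp.
log_truncated_pdf <- function(t, weights, lifetimes, t_min, t_max) {
  z <- window_mass(weights, lifetimes, t_min, t_max)
  lw <- log(weights) - log(lifetimes)
  m <- outer(t, -1 / lifetimes)
  m <- sweep(m, 2L, lw, "+")
  row_logsumexp(m) - log(z)
}

#' Negative log-likelihood of a dwell-time dataset
#'
#' Sum of `-log(truncated_pdf(t_i))` over the un-binned event durations.
#' This is the objective minimized by [fit_mixture()].
#'
#' @param data A [dwell_dataset()].
#' @param model A [mixture_model()].
#' @return Negative log-likelihood in nats (finite for valid inputs).
#' @export
neg_log_likelihood <- function(data, model) {
  stopifnot(inherits(data, "dwell_dataset"), inherits(model, "mixture_model"))
  t <- data$durations
  if (length(t) == 0L) stop("empty dataset: nothing to evaluate")
  w <- data$window
  tol <- 1e-9
  bad <- which(t < w$t_min - tol | t > w$t_max + tol)
  if (length(bad) > 0L) {
    stop("durations outside the observation window at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  nll <- -sum(log_truncated_pdf(t, model$weights, model$lifetimes,
                                w$t_min, w$t_max))
  if (!is.finite(nll)) stop("non-finite log-likelihood")
  nll
}
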