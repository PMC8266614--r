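#' Normalize a decay series to its reference signal
#'
#' Divides the target signal by the reference signal at each time point and
#' rescales so the time-0 ratio equals 100%:
#' `percent[i] = 100 * (target[i]/reference[i]) / (target[1]/reference[1])`.
#' The result is invariant to rescaling either signal by a positive
#' constant.  A series whose percent-remaining rises above 100% is flagged
#' as non-decaying.
#'
#' @param series A [decay_series()].
#' @return The series with a `percent_remaining` column added and attributes
#'   `normalized = TRUE` and `non_decaying` (TRUE when any point exceeds
#'   100% beyond rounding error).
#' @export
normalize_to_reference <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  if (any(series$reference_signal <= 0)) {
    stop("reference signal must be strictly positive at all times")
  }
  ratio <- series$target_signal / series$reference_signal
  series$percent_remaining <- 100 * ratio / ratio[1L]
  attr(series, "normalized") <- TRUE
  attr(series, "non_decaying") <- any(series$percent_remaining > 100 + 1e-9)
  series
}

ensure_normalized <- function(series) {
  if (!isTRUE(attr(series, "normalized"))) {
    series <- normalize_to_reference(series)
  }
  series
}

# R-squared computed directly from the fit (summary.lm warns on noiseless
# series); a zero-variance response is reported as a perfect fit.
r_squared_of <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(1)
  min(max(1 - sum(stats::resid(fit)^2) / ss_tot, 0), 1)
}

halflife_result <- function(method, rate, half_life, r_squared, n_points,
                            no_decay = FALSE, fit = NULL) {
  structure(list(method = method, rate = rate, half_life = half_life,
                 r_squared = r_squared, n_points = n_points,
                 no_decay = no_decay, fit = fit),
            class = "halflife_result")
}

#' @export
print.halflife_result <- function(x, ...) {
  if (x$no_decay) {
    cat(sprintf("Half-life (%s): no decay detected (rate <= 0)\n", x$method))
  } else {
    unit <- if (x$method == "first_order") "1/min" else "%/min"
    cat(sprintf("Half-life (%s): t1/2 = %.4g min | rate = %.4g %s | R^2 = %.4f (n = %d)\n",
                x$method, x$half_life, x$rate, unit, x$r_squared, x$n_points))
  }
  invisible(x)
}

#' First-order (exponential trendline) half-life
#'
#' Fits ordinary least squares of `log(percent_remaining)` on time — the
#' spreadsheet "exponential trendline" convention — and reports
#' `k_decay = -slope` (1/min) and `t1/2 = ln2 / k_decay`, with R-squared on
#' the log scale.
#'
#' @param series A [decay_series()]; normalized internally when needed.
#' @return A `halflife_result` with `method = "first_order"`.  When the
#'   fitted slope is non-negative the result carries `no_decay = TRUE` and
#'   no half-life.
#' @examples
#' fit_first_order(simulate_decay(1.7, 0:8, "first_order"))
#' @export
fit_first_order <- function(series) {
  series <- ensure_normalized(series)
  n <- nrow(series)
  if (n < 3L) stop("insufficient points: need at least 3 time points")
  bad <- which(series$percent_remaining <= 0)
  if (length(bad) > 0L) {
    stop("non-positive percent remaining at time point(s) ",
         paste(series$time_min[bad], collapse = ", "),
         " min; the exponential trendline requires positive values")
  }
  fit <- stats::lm(log(percent_remaining) ~ time_min, data = series)
  k <- -unname(stats::coef(fit)[2L])
  r2 <- r_squared_of(fit)
  if (!(k > 0)) {
    return(halflife_result("first_order", k, NA_real_, r2, n,
                           no_decay = TRUE, fit = fit))
  }
  halflife_result("first_order", k, log(2) / k, r2, n, fit = fit)
}

#' Linear-trendline half-life
#'
#' Fits ordinary least squares of `percent_remaining` on time and reports
#' the decay slope `k* = -slope` in %/min and `t1/2 = 50 / k*`, with
#' R-squared on the linear scale.  This is the fallback estimator when
#' decay is not first-order.
#'
#' @param series A [decay_series()]; normalized internally when needed.
#' @return A `halflife_result` with `method = "linear"`; `no_decay = TRUE`
#'   when the slope is non-negative.
#' @examples
#' fit_linear(simulate_decay(10.4, 0:8, "linear"))
#' @export
fit_linear <- function(series) {
  series <- ensure_normalized(series)
  n <- nrow(series)
  if (n < 3L) stop("insufficient points: need at least 3 time points")
  fit <- stats::lm(percent_remaining ~ time_min, data = series)
  kstar <- -unname(stats::coef(fit)[2L])
  r2 <- r_squared_of(fit)
  if (!(kstar > 0)) {
    return(halflife_result("linear", kstar, NA_real_, r2, n,
                           no_decay = TRUE, fit = fit))
  }
  halflife_result("linear", kstar, 50 / kstar, r2, n, fit = fit)
}

#' Choose between first-order and linear half-life estimators
#'
#' Computes both candidate fits and returns the first-order result when its
#' log-scale R-squared meets the adequacy threshold (default 0.90) and the
#' series actually decays; otherwise returns the linear-trendline result.
#' Mirrors the judgement that a transcript "not degraded with first-order
#' kinetics" should be summarized by the linear estimator.
#'
#' @param series A [decay_series()]; normalized internally when needed.
#' @param r2_threshold Minimum log-scale R-squared for first-order adequacy.
#' @return The selected `halflife_result` with both candidates attached as
#'   `$candidates` (a list with elements `first_order` and `linear`; the
#'   first-order slot may hold an error message when that fit is
#'   infeasible, e.g. zero or negative percentages).
#' @export
choose_method <- function(series, r2_threshold = 0.90) {
  series <- ensure_normalized(series)
  if (nrow(series) < 3L) stop("insufficient points: need at least 3 time points")
  fo <- tryCatch(fit_first_order(series), error = function(e) conditionMessage(e))
  lin <- fit_linear(series)
  use_fo <- inherits(fo, "halflife_result") && !fo$no_decay &&
    fo$r_squared >= r2_threshold
  out <- if (use_fo) fo else lin
  out$candidates <- list(first_order = fo, linear = lin)
  out
}
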