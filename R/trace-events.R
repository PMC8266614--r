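#' Event-calling configuration
#'
#' Rules for converting per-frame intensity traces into binding events.
#'
#' @param threshold_rule `"k_sigma_above_baseline"` (default) sets the
#'   threshold at baseline mean plus `threshold_value` standard deviations,
#'   both estimated from the lowest-intensity 20% of frames;
#'   `"absolute"` uses `threshold_value` directly in intensity units.
#' @param threshold_value Sigma multiple (default 3) or absolute intensity.
#' @param min_frames Minimum run length in frames for a valid event (>= 1).
#' @param gap_tolerance_frames Dark gaps up to this many frames inside a run
#'   are bridged; the default 0 means a single dark frame ends an event.
#' @return An object of class `event_call_config`.
#' @export
event_call_config <- function(threshold_rule = c("k_sigma_above_baseline",
                                                 "absolute"),
                              threshold_value = 3, min_frames = 1L,
                              gap_tolerance_frames = 0L) {
  threshold_rule <- match.arg(threshold_rule)
  if (!(is.numeric(min_frames) && min_frames >= 1)) {
    stop_field("min_frames", "must be >= 1")
  }
  if (!(is.numeric(gap_tolerance_frames) && gap_tolerance_frames >= 0)) {
    stop_field("gap_tolerance_frames", "must be >= 0")
  }
  structure(list(threshold_rule = threshold_rule,
                 threshold_value = as.numeric(threshold_value),
                 min_frames = as.integer(min_frames),
                 gap_tolerance_frames = as.integer(gap_tolerance_frames)),
            class = "event_call_config")
}

# Frame indices of bound runs after gap bridging: returns a data.frame with
# columns first, last (1-based frame indices).
bound_runs <- function(bound, gap_tol) {
  idx <- which(bound)
  if (length(idx) == 0L) return(data.frame(first = integer(0), last = integer(0)))
  brk <- which(diff(idx) > gap_tol + 1L)
  first <- idx[c(1L, brk + 1L)]
  last <- idx[c(brk, length(idx))]
  data.frame(first = first, last = last)
}

#' Call binding events from intensity traces
#'
#' Binarizes each trace at the configured threshold, merges bound runs
#' separated by gaps within the tolerance, and converts each surviving run
#' into a dwell time (`run length in frames * frame_interval`).  Events
#' shorter than the window's minimum resolvable interval are dropped; events
#' touching the final frame are treated per `censoring_policy` because their
#' true duration is right-censored by the recording.
#'
#' @param traces A [trace_set()].
#' @param config An [event_call_config()].
#' @param window An [obs_window()].
#' @param condition Condition label for the resulting dataset.
#' @param censoring_policy `"drop_incomplete"` (default) or `"cap_at_window"`
#'   for events still bound at the last frame.
#' @return A [dwell_dataset()] with molecule ids and event onsets retained.
#' @export
call_events <- function(traces, config = event_call_config(), window,
                        condition = "called",
                        censoring_policy = c("drop_incomplete",
                                             "cap_at_window")) {
  stopifnot(inherits(traces, "trace_set"),
            inherits(config, "event_call_config"),
            inherits(window, "obs_window"))
  censoring_policy <- match.arg(censoring_policy)
  if (length(traces$traces) == 0L) stop("empty trace set")
  fi <- traces$frame_interval

  mol <- integer(0); st <- numeric(0); dur <- numeric(0)
  n_short <- 0L; n_long <- 0L
  for (i in seq_along(traces$traces)) {
    x <- traces$traces[[i]]
    thr <- if (config$threshold_rule == "absolute") {
      config$threshold_value
    } else {
      # Baseline statistics from the lowest-intensity 20% of frames.  That
      # subset is the lower tail of the baseline noise, so its mean and sd
      # are corrected for the truncation assuming Gaussian noise:
      # for the tail below the 20% quantile z0 = qnorm(0.2), the tail mean is
      # mu + m*sigma and the tail sd is sqrt(v)*sigma with
      # m = -dnorm(z0)/0.2 and v = 1 + z0*m - m^2.
      n_low <- max(2L, ceiling(0.2 * length(x)))
      low <- sort(x)[seq_len(n_low)]
      s_low <- stats::sd(low)
      if (!is.finite(s_low) || s_low == 0) {
        stop("cannot apply the k-sigma threshold rule: baseline sigma is zero ",
             "(constant trace ", i, ")")
      }
      z0 <- stats::qnorm(0.2)
      m <- -stats::dnorm(z0) / 0.2
      v <- 1 + z0 * m - m^2
      sigma_hat <- s_low / sqrt(v)
      mu_hat <- mean(low) - m * sigma_hat
      mu_hat + config$threshold_value * sigma_hat
    }
    runs <- bound_runs(x > thr, config$gap_tolerance_frames)
    if (nrow(runs) == 0L) next
    len <- runs$last - runs$first + 1L
    keep <- len >= config$min_frames
    runs <- runs[keep, , drop = FALSE]; len <- len[keep]
    if (nrow(runs) == 0L) next

    d <- len * fi
    # right-censored: event still bound at the final frame
    censored <- runs$last == length(x)
    if (censoring_policy == "drop_incomplete") {
      n_long <- n_long + sum(censored)
      runs <- runs[!censored, , drop = FALSE]
      d <- d[!censored]
    } else {
      d <- pmin(d, window$t_max)
    }
    too_short <- d < window$t_min - 1e-9
    n_short <- n_short + sum(too_short)
    runs <- runs[!too_short, , drop = FALSE]
    d <- d[!too_short]
    d <- pmin(d, window$t_max)
    if (length(d) == 0L) next
    mol <- c(mol, rep.int(i, length(d)))
    st <- c(st, (runs$first - 1L) * fi)
    dur <- c(dur, d)
  }
  dwell_dataset(durations = dur, window = window, condition = condition,
                molecule_id = if (length(mol)) mol else NULL,
                start_s = if (length(st)) st else NULL,
                n_discarded_short = n_short, n_discarded_long = n_long)
}
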