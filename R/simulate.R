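#' Simulation configuration
#'
#' Bundles the acquisition parameters shared by the simulators: number of
#' raw binding events to draw, camera frame interval, optional fluorophore
#' photobleaching lifetime, RNG seed, and the policy for events still bound
#' at the end of the observation window.
#'
#' @param n_events Number of raw binding events to draw (before window
#'   filtering); must be positive.
#' @param frame_interval Camera frame interval in seconds; default 0.1 s.
#' @param bleach_lifetime Photobleaching lifetime of the dye in seconds
#'   (`NULL` disables bleaching).  The canonical Cy5 value in this assay is
#'   173 s.
#' @param seed Integer RNG seed.
#' @param censoring_policy `"drop_incomplete"` discards events that extend
#'   beyond `t_max` (the default, matching a density normalized over
#'   \[`t_min`, `t_max`\]); `"cap_at_window"` records them with duration
#'   `t_max` instead (for sensitivity analysis).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_events, frame_interval = 0.1, bleach_lifetime = NULL,
                       seed = 1L,
                       censoring_policy = c("drop_incomplete", "cap_at_window")) {
  censoring_policy <- match.arg(censoring_policy)
  if (!(is.numeric(n_events) && length(n_events) == 1L && n_events > 0)) {
    stop_field("n_events", "must be a positive count")
  }
  if (!(is.numeric(frame_interval) && frame_interval > 0)) {
    stop_field("frame_interval", "must be strictly positive")
  }
  if (!is.null(bleach_lifetime) && !(is.numeric(bleach_lifetime) &&
                                     bleach_lifetime > 0)) {
    stop_field("bleach_lifetime", "must be strictly positive when enabled")
  }
  structure(list(n_events = as.integer(n_events),
                 frame_interval = as.numeric(frame_interval),
                 bleach_lifetime = bleach_lifetime,
                 seed = as.integer(seed),
                 censoring_policy = censoring_policy),
            class = "sim_config")
}

#' Simulate dwell times from an exponential mixture under an observation window
#'
#' Draws binding events from the mixture (component k chosen with probability
#' `weights[k]`, duration exponential with mean `lifetimes[k]`), optionally
#' truncates each by a competing exponential photobleaching time, applies the
#' window filters and frame quantization, and returns the surviving dwell
#' times as a [dwell_dataset()].
#'
#' @details
#' The observation process is modelled in this order:
#' \enumerate{
#'   \item binding duration drawn from the mixture;
#'   \item if bleaching is enabled, the observed duration is the minimum of
#'     the binding duration and an exponential bleach time (competing
#'     first-order processes, applied independently per event);
#'   \item events shorter than `window$t_min` are discarded (unresolvable);
#'   \item surviving durations are rounded \emph{up} to the next full frame
#'     (an event must occupy a frame to be seen);
#'   \item events extending beyond `window$t_max` are discarded or capped
#'     according to `config$censoring_policy`.
#' }
#' Discard counts are recorded on the returned dataset.  Event onset times
#' are drawn uniformly over the part of the recording that can contain the
#' event, and events are spread over roughly `n_events / 5` molecules; both
#' serve visualization (rastergrams) and per-molecule resampling, not the
#' likelihood.
#'
#' @param model A [mixture_model()].
#' @param window An [obs_window()].
#' @param config A [sim_config()].
#' @param condition Condition label attached to the dataset.
#' @return A [dwell_dataset()].
#' @examples
#' m <- mixture_model(c(0.56, 0.44), c(2, 60))
#' d <- simulate_dwells(m, obs_window(0.1, 180), sim_config(1000, seed = 1))
#' @export
simulate_dwells <- function(model, window, config, condition = "simulated") {
  stopifnot(inherits(model, "mixture_model"), inherits(window, "obs_window"),
            inherits(config, "sim_config"))
  n <- config$n_events
  fi <- config$frame_interval
  draws <- with_seed(config$seed, {
    comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
    raw <- stats::rexp(n, rate = 1 / model$lifetimes[comp])
    if (!is.null(config$bleach_lifetime)) {
      raw <- pmin(raw, stats::rexp(n, rate = 1 / config$bleach_lifetime))
    }
    # onset/molecule assignment drawn inside the same seeded stream so the
    # whole dataset is reproducible bit-for-bit
    mol <- sample.int(max(1L, ceiling(n / 5)), n, replace = TRUE)
    u_start <- stats::runif(n)
    list(raw = raw, mol = mol, u_start = u_start)
  })
  raw <- draws$raw

  keep_min <- raw >= window$t_min
  n_short <- sum(!keep_min)
  if (!any(keep_min)) {
    stop("no events survived the minimum resolvable interval filter (t_min = ",
         window$t_min, " s)")
  }
  q <- ceiling(raw[keep_min] / fi - 1e-9) * fi

  n_long <- 0L
  if (config$censoring_policy == "drop_incomplete") {
    keep_max <- q <= window$t_max + 1e-9
    n_long <- sum(!keep_max)
    if (!any(keep_max)) {
      stop("no events survived the observation-window filter (t_max = ",
           window$t_max, " s)")
    }
    q <- q[keep_max]
    idx <- which(keep_min)[keep_max]
  } else {
    q <- pmin(q, window$t_max)
    idx <- which(keep_min)
  }

  max_start <- pmax(window$t_max - q, 0)
  dwell_dataset(durations = q,
                window = window,
                condition = condition,
                molecule_id = draws$mol[idx],
                start_s = draws$u_start[idx] * max_start,
                n_discarded_short = n_short,
                n_discarded_long = n_long)
}

#' Trace set: per-molecule fluorescence intensity time series
#'
#' Constructed by [simulate_traces()] (carrying its ground-truth event
#' schedule) or by [read_trace_table()].
#'
#' @param traces List of numeric intensity vectors, one per molecule; frame
#'   indices run contiguously from 0.
#' @param frame_interval Frame interval in seconds.
#' @param ground_truth Optional list of data frames with columns `start_s`,
#'   `end_s` giving the planted events per molecule.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, frame_interval, ground_truth = NULL) {
  stopifnot(is.list(traces), length(traces) > 0L)
  if (any(!vapply(traces, function(x) all(is.finite(x)), logical(1L)))) {
    stop("intensities must be finite")
  }
  structure(list(traces = traces,
                 frame_interval = as.numeric(frame_interval),
                 ground_truth = ground_truth),
            class = "trace_set")
}

#' Simulate fluorescence intensity traces with planted binding events
#'
#' Generates a per-frame intensity trace for each molecule: baseline plus a
#' fixed amplitude while a binding event is in progress, plus Gaussian noise
#' with standard deviation `amplitude / snr`.  A frame counts as bound when
#' its midpoint falls inside an event.  The planted schedule is retained as
#' ground truth for evaluating event calling.
#'
#' @param schedule List (one entry per molecule) of data frames with columns
#'   `start_s` and `end_s` in seconds; events on a molecule must not overlap
#'   and must lie within the recording.
#' @param config A [sim_config()]; supplies `frame_interval` and `seed`.
#' @param snr Signal-to-noise ratio (event amplitude over noise sd); > 0.
#' @param n_frames Number of frames per trace (default 1800, a 3-minute
#'   movie at 0.1 s frames).
#' @param baseline Baseline intensity (a.u.).
#' @param amplitude Event amplitude above baseline (a.u.).
#' @return A [trace_set()] with ground truth attached.
#' @export
simulate_traces <- function(schedule, config, snr, n_frames = 1800L,
                            baseline = 100, amplitude = 1000) {
  stopifnot(inherits(config, "sim_config"), is.list(schedule))
  if (!(is.numeric(snr) && snr > 0)) stop_field("snr", "must be > 0")
  fi <- config$frame_interval
  t_end <- n_frames * fi
  schedule <- lapply(schedule, function(ev) {
    if (is.null(ev) || nrow(ev) == 0L) {
      return(data.frame(start_s = numeric(0), end_s = numeric(0)))
    }
    ev <- ev[order(ev$start_s), , drop = FALSE]
    if (any(ev$start_s < 0) || any(ev$end_s > t_end + 1e-9)) {
      stop("event outside the recording [0, ", t_end, "] s")
    }
    if (any(ev$end_s <= ev$start_s)) stop("events must have positive duration")
    if (nrow(ev) > 1L && any(ev$start_s[-1L] < ev$end_s[-nrow(ev)] - 1e-9)) {
      stop("overlapping events on one molecule")
    }
    ev
  })
  mid <- (seq_len(n_frames) - 0.5) * fi
  noise_sd <- amplitude / snr
  traces <- with_seed(config$seed, {
    lapply(schedule, function(ev) {
      bound <- rep(FALSE, n_frames)
      for (j in seq_len(nrow(ev))) {
        bound <- bound | (mid >= ev$start_s[j] & mid < ev$end_s[j])
      }
      baseline + amplitude * bound + stats::rnorm(n_frames, sd = noise_sd)
    })
  })
  trace_set(traces, fi, ground_truth = schedule)
}

#' Decay time series (rifampicin chase)
#'
#' Holds a target-RNA signal and a reference (16S rRNA) signal over time
#' after transcription shut-off.  [normalize_to_reference()] derives the
#' percent-remaining column.
#'
#' @param time_min Sampling times in minutes, strictly increasing, first
#'   value 0 (the rifampicin-addition sample).
#' @param target_signal Target RNA signal (a.u.), strictly positive.
#' @param reference_signal Reference RNA signal (a.u.), strictly positive.
#' @return A data frame of class `decay_series`.
#' @export
decay_series <- function(time_min, target_signal, reference_signal) {
  time_min <- as.numeric(time_min)
  target_signal <- as.numeric(target_signal)
  reference_signal <- as.numeric(reference_signal)
  n <- length(time_min)
  if (n < 1L || length(target_signal) != n || length(reference_signal) != n) {
    stop("time, target and reference vectors must have equal length")
  }
  if (time_min[1L] != 0) stop("times must start at 0 (rifampicin addition)")
  if (n > 1L && any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(!is.finite(target_signal)) || any(target_signal <= 0)) {
    stop("target signal must be positive and finite")
  }
  if (any(!is.finite(reference_signal)) || any(reference_signal <= 0)) {
    stop("reference signal must be positive and finite")
  }
  structure(data.frame(time_min = time_min,
                       target_signal = target_signal,
                       reference_signal = reference_signal),
            class = c("decay_series", "data.frame"))
}

#' Simulate an mRNA decay time course
#'
#' Generates target and reference signals whose reference-normalized
#' percent-remaining curve follows either first-order (exponential) decay,
#' `100 * exp(-ln2/t_half * t)`, or linear decay, `100 - (50/t_half) * t`
#' (floored at a small positive value).  Optional multiplicative Gaussian
#' noise is applied to the target signal.
#'
#' @param half_life Half-life in minutes (> 0).
#' @param times Sampling times in minutes starting at 0.
#' @param shape `"first_order"` or `"linear"`.
#' @param noise_sd Multiplicative noise on the target signal, as a percent
#'   (0 for a noiseless series).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param reference_level Constant reference signal level (a.u.).
#' @return A [decay_series()].
#' @examples
#' s <- simulate_decay(1.7, 0:8, "first_order")
#' @export
simulate_decay <- function(half_life, times,
                           shape = c("first_order", "linear"),
                           noise_sd = 0, seed = 1L, reference_level = 1000) {
  shape <- match.arg(shape)
  if (!(is.numeric(half_life) && half_life > 0)) {
    stop_field("half_life", "must be > 0")
  }
  times <- as.numeric(times)
  if (length(times) < 1L || times[1L] != 0) {
    stop("times must start at 0 (rifampicin addition)")
  }
  percent <- switch(shape,
    first_order = 100 * exp(-log(2) / half_life * times),
    linear = pmax(100 - (50 / half_life) * times, 1e-3))
  reference <- rep(reference_level, length(times))
  target <- reference * percent / 100
  if (noise_sd > 0) {
    fac <- with_seed(seed, 1 + stats::rnorm(length(times), sd = noise_sd / 100))
    target <- target * pmax(fac, 1e-6)
  }
  out <- decay_series(times, target, reference)
  attr(out, "true_half_life") <- half_life
  attr(out, "shape") <- shape
  out
}
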