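# Delimited-text I/O for the three table schemas and JSON result documents.
#
# Dwell tables:  molecule_id, condition, dwell_s  (optional start_s)
# Trace tables:  trace_id, frame, intensity
# Decay tables:  time_min, target_signal, reference_signal
# All tab-separated by default, header required, UTF-8, '.' decimal.

#' Write a dwell-time table
#'
#' @param data A [dwell_dataset()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_dwell_table <- function(data, path, sep = "\t") {
  stopifnot(inherits(data, "dwell_dataset"))
  df <- data.frame(
    molecule_id = data$molecule_id %||% seq_along(data$durations),
    condition = rep(data$condition, length(data$durations)),
    dwell_s = data$durations)
  if (!is.null(data$start_s)) df$start_s <- data$start_s
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dwell-time table
#'
#' @param path File with header columns `molecule_id`, `condition`,
#'   `dwell_s` (optional `start_s`).
#' @param window The [obs_window()] the dwells were recorded in.
#' @param sep Field separator (default tab).
#' @return A [dwell_dataset()] (single condition per file).
#' @export
read_dwell_table <- function(path, window, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "condition", "dwell_s")
  if (!all(need %in% names(df))) {
    stop("dwell table must have header columns: ", paste(need, collapse = ", "))
  }
  cond <- unique(df$condition)
  if (length(cond) > 1L) {
    stop("dwell table mixes conditions: ", paste(cond, collapse = ", "))
  }
  dwell_dataset(df$dwell_s, window, condition = cond,
                molecule_id = df$molecule_id,
                start_s = if ("start_s" %in% names(df)) df$start_s else NULL)
}

#' Write a trace table
#'
#' @param traces A [trace_set()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, sep = "\t") {
  stopifnot(inherits(traces, "trace_set"))
  df <- do.call(rbind, lapply(seq_along(traces$traces), function(i) {
    x <- traces$traces[[i]]
    data.frame(trace_id = i, frame = seq_along(x) - 1L, intensity = x)
  }))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace table
#'
#' @param path File with header columns `trace_id`, `frame`, `intensity`.
#' @param frame_interval Frame interval in seconds.
#' @param sep Field separator (default tab).
#' @return A [trace_set()].
#' @export
read_trace_table <- function(path, frame_interval = 0.1, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "intensity")
  if (!all(need %in% names(df))) {
    stop("trace table must have header columns: ", paste(need, collapse = ", "))
  }
  traces <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (!identical(as.integer(d$frame), seq_len(nrow(d)) - 1L)) {
      stop("frame indices must be contiguous from 0 (trace ", d$trace_id[1L], ")")
    }
    d$intensity
  })
  trace_set(unname(traces), frame_interval)
}

#' Write a decay table
#'
#' @param series A [decay_series()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_decay_table <- function(series, path, sep = "\t") {
  stopifnot(inherits(series, "decay_series"))
  utils::write.table(series[, c("time_min", "target_signal",
                                "reference_signal")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a decay table
#'
#' @param path File with header columns `time_min`, `target_signal`,
#'   `reference_signal`.
#' @param sep Field separator (default tab).
#' @return A [decay_series()].
#' @export
read_decay_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_min", "target_signal", "reference_signal")
  if (!all(need %in% names(df))) {
    stop("decay table must have header columns: ", paste(need, collapse = ", "))
  }
  decay_series(df$time_min, df$target_signal, df$reference_signal)
}

# Recursively round numeric leaves to 6 significant digits.
round_signif <- function(x, digits = 6L) {
  if (is.list(x)) return(lapply(x, round_signif, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

#' Write a result document as JSON
#'
#' Serializes a result list with two blocks: `summary` (numerics rounded to
#' 6 significant digits for readability) and `machine` (full precision).
#' Data frames are stored column-wise so they round-trip exactly.
#'
#' @param x A named list (e.g. from [as_result_list()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  doc <- list(summary = round_signif(x), machine = x)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result document written by [write_result_json()]
#'
#' @param path JSON file path.
#' @param block `"machine"` (default, full precision) or `"summary"`.
#' @return The stored list.
#' @export
read_result_json <- function(path, block = c("machine", "summary")) {
  block <- match.arg(block)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc[[block]]
}

#' Convert fitted objects to plain lists for serialization
#'
#' @param x A `fit_result`, `bootstrap_summary`, `comparison_result` or
#'   `halflife_result`.
#' @return A named list of plain vectors/data frames suitable for
#'   [write_result_json()].
#' @export
as_result_list <- function(x) {
  UseMethod("as_result_list")
}

#' @export
as_result_list.fit_result <- function(x) {
  list(type = "mixture_fit", condition = x$condition, K = x$K,
       weights = x$model$weights, lifetimes_s = x$model$lifetimes,
       window = list(t_min = x$window$t_min, t_max = x$window$t_max),
       log_likelihood = x$log_likelihood, bic = x$bic,
       n_events = x$n_events, converged = x$converged,
       n_starts_used = x$n_starts_used,
       identifiability_warning = x$identifiability_warning,
       seed = x$seed,
       bic_table = x$bic_table)
}

#' @export
as_result_list.bootstrap_summary <- function(x) {
  list(type = "bootstrap", n_boot = x$n_boot, failures = x$failures,
       valid = x$valid, summary = x$summary, seed = x$seed,
       base = as_result_list(x$base_fit))
}

#' @export
as_result_list.comparison_result <- function(x) {
  list(type = "comparison", parameter = x$parameter, labels = x$labels,
       estimate_a = x$estimate_a, estimate_b = x$estimate_b,
       difference = x$difference, statistic = x$statistic,
       p_value = x$p_value, significant = x$significant,
       df_policy = x$df_policy, degenerate = x$degenerate)
}

#' @export
as_result_list.halflife_result <- function(x) {
  list(type = "halflife", method = x$method, rate = x$rate,
       half_life_min = x$half_life, r_squared = x$r_squared,
       n_points = x$n_points, no_decay = x$no_decay)
}
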