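# Figure-style outputs: rastergrams, dwell-time survival curves, decay
# curves.  All return ggplot objects; render_* helpers write image files.

#' Rastergram of binding events
#'
#' Horizontal-bar plot of binding events per molecule over the recording
#' window, for a random selection of molecules (the study convention shows
#' 50 randomly selected traces).
#'
#' @param data A [dwell_dataset()] carrying `molecule_id` and `start_s`.
#' @param selection_size Number of molecules to show (default 50).  When
#'   fewer are available, all are shown with a warning.
#' @param seed Seed for the random selection (deterministic).
#' @return A ggplot object; its data has one row per plotted event.
#' @export
plot_rastergram <- function(data, selection_size = 50L, seed = 1L) {
  stopifnot(inherits(data, "dwell_dataset"))
  if (length(data$durations) == 0L) stop("empty dataset: nothing to plot")
  if (is.null(data$molecule_id) || is.null(data$start_s)) {
    stop("rastergram needs per-event molecule ids and onset times")
  }
  ids <- unique(data$molecule_id)
  if (length(ids) < selection_size) {
    warning(sprintf("only %d molecules available; showing all (requested %d)",
                    length(ids), selection_size), call. = FALSE)
    pick <- ids
  } else {
    pick <- with_seed(seed, sample(ids, selection_size))
  }
  keep <- data$molecule_id %in% pick
  df <- data.frame(molecule_id = data$molecule_id[keep],
                   start_s = data$start_s[keep],
                   end_s = data$start_s[keep] + data$durations[keep])
  df$row <- match(df$molecule_id, pick)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                                   y = .data$row, yend = .data$row)) +
    ggplot2::geom_segment(linewidth = 1.2, colour = "#b2182b") +
    ggplot2::scale_x_continuous(limits = c(0, data$window$t_max)) +
    ggplot2::labs(x = "Time (s)", y = "Molecule",
                  title = sprintf("Binding events: %s", data$condition)) +
    ggplot2::theme_classic()
}

#' Render a rastergram to an image file
#'
#' @inheritParams plot_rastergram
#' @param file Output image path (format from extension, e.g. `.png`).
#' @param width,height Figure size in inches.
#' @return `file`, invisibly.
#' @export
render_rastergram <- function(data, file, selection_size = 50L, seed = 1L,
                              width = 6, height = 4) {
  p <- plot_rastergram(data, selection_size = selection_size, seed = seed)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(file)
}

#' Dwell-time survival curves with fitted models
#'
#' Empirical survival (1 - ECDF) of the dwell times on a log-log scale,
#' optionally overlaid with the survival implied by fitted truncated
#' mixtures.
#'
#' @param datasets A [dwell_dataset()] or list of them.
#' @param fits Optional `fit_result` or list of them (same order).
#' @return A ggplot object.
#' @export
plot_dwell_survival <- function(datasets, fits = NULL) {
  if (inherits(datasets, "dwell_dataset")) datasets <- list(datasets)
  if (inherits(fits, "fit_result")) fits <- list(fits)
  emp <- do.call(rbind, lapply(datasets, function(d) {
    t_sorted <- sort(d$durations)
    data.frame(condition = d$condition, t = t_sorted,
               survival = 1 - (seq_along(t_sorted) - 0.5) / length(t_sorted))
  }))
  p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$t, y = .data$survival,
                                         colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dwell time (s)", y = "Survival") +
    ggplot2::theme_classic()
  if (!is.null(fits)) {
    mod <- do.call(rbind, lapply(fits, function(f) {
      tt <- exp(seq(log(f$window$t_min), log(min(f$window$t_max, 1e4)),
                    length.out = 200L))
      data.frame(condition = f$condition, t = tt,
                 survival = 1 - truncated_cdf(tt, f$model, f$window))
    }))
    mod <- mod[mod$survival > 0, , drop = FALSE]
    p <- p + ggplot2::geom_line(data = mod, linetype = "dashed")
  }
  p
}

#' Decay curve with fitted trendline
#'
#' Percent-remaining time course with the selected half-life fit overlaid.
#'
#' @param series A normalized [decay_series()].
#' @param fit Optional `halflife_result` for the trendline.
#' @return A ggplot object.
#' @export
plot_decay <- function(series, fit = NULL) {
  series <- ensure_normalized(series)
  p <- ggplot2::ggplot(as.data.frame(series),
                       ggplot2::aes(x = .data$time_min,
                                    y = .data$percent_remaining)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time after rifampicin (min)", y = "mRNA remaining (%)") +
    ggplot2::theme_classic()
  if (!is.null(fit) && !fit$no_decay) {
    tt <- seq(min(series$time_min), max(series$time_min), length.out = 100L)
    yy <- if (fit$method == "first_order") {
      100 * exp(-fit$rate * tt)
    } else {
      pmax(100 - fit$rate * tt, 0)
    }
    p <- p + ggplot2::geom_line(data = data.frame(time_min = tt,
                                                  percent_remaining = yy),
                                colour = "#2166ac")
  }
  p
}
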