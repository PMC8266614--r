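#!/usr/bin/env Rscript

# Stage 6: figure-style outputs.  Rastergrams of 50 randomly selected
# molecules per condition, dwell-time survival curves with the fitted
# truncated mixtures overlaid, and the decay curves with their trendlines.
# Writes PNGs under results/figures/.

suppressPackageStartupMessages(library(dwellmix))

data_dir <- "results/data"
out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

acq <- acquisition_defaults()
window <- obs_window(acq$t_min, acq$t_max)
conds <- c("amiE102", "amiE102_Crc", "amiE_3ARNmut")

datasets <- lapply(conds, function(cond) {
  read_dwell_table(file.path(data_dir, paste0(cond, "_dwells.tsv")), window)
})
names(datasets) <- conds

for (cond in conds) {
  render_rastergram(datasets[[cond]],
                    file.path(out, paste0(cond, "_rastergram.png")),
                    selection_size = 50, seed = 601)
  message("wrote ", cond, " rastergram")
}

ks <- c(amiE102 = 2, amiE102_Crc = 2, amiE_3ARNmut = 3)
fits <- lapply(conds, function(cond) {
  fit_mixture(datasets[[cond]], K = ks[[cond]], n_starts = 20, seed = 602)
})
p_surv <- plot_dwell_survival(datasets, fits)
ggplot2::ggsave(file.path(out, "dwell_survival.png"), p_surv,
                width = 6, height = 4, dpi = 150)
message("wrote survival curves")

for (nm in c("PAO1", "PAO1_dcrc")) {
  s <- normalize_to_reference(
    read_decay_table(file.path("results/decay", paste0(nm, "_noisy_decay.tsv"))))
  hl <- choose_method(s)
  p <- plot_decay(s, hl)
  ggplot2::ggsave(file.path(out, paste0(nm, "_decay.png")), p,
                  width = 5, height = 4, dpi = 150)
  message("wrote ", nm, " decay figure")
}
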