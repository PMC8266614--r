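test_that("residual-amplitude error propagation is Pythagorean", {
  expect_equal(propagate_residual_sigma(3, 4), 5)
  expect_equal(propagate_residual_sigma(0, 0), 0)
  expect_equal(propagate_residual_sigma(0.04, 0.05), 0.0640312423743,
               tolerance = 1e-9)
  expect_error(propagate_residual_sigma(-0.1, 0.2), "non-negative")
})

test_that("histogram error bars follow the binomial standard deviation", {
  expect_equal(histogram_bar_sigma(100, 0.5), 5)
  expect_equal(histogram_bar_sigma(12345, 0), 0)
  expect_equal(histogram_bar_sigma(500, 0.56), 11.0995495404, tolerance = 1e-9)
  expect_error(histogram_bar_sigma(100, 1.2), "\\[0, 1\\]")
  expect_error(histogram_bar_sigma(-5, 0.5), "non-negative")
})

test_that("condition comparison computes the two-tailed test correctly", {
  # identical estimates
  same <- compare_conditions(0.5, 0.02, 0.5, 0.02)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # the study's stable-fraction shift: 0.44 +/- 0.05 without Crc versus
  # 0.70 +/- 0.04 with Crc is significant at 0.05
  crc <- compare_conditions(0.44, 0.05, 0.70, 0.04,
                            parameter = "a_long",
                            labels = c("no_Crc", "Crc_100nM"))
  expect_lt(crc$p_value, 0.05)
  expect_true(crc$significant)

  # borderline z reproduces the canonical normal quantile
  z <- compare_conditions(1.959964, 1, 0, 0)
  expect_equal(z$statistic, 1.959964)
  expect_equal(z$p_value, 0.05, tolerance = 1e-4)

  # antisymmetry: swapping conditions flips the sign, not the p value
  ab <- compare_conditions(0.3, 0.02, 0.5, 0.03)
  ba <- compare_conditions(0.5, 0.03, 0.3, 0.02)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)

  # degenerate branches
  deg <- compare_conditions(0.3, 0, 0.5, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_equal(compare_conditions(0.3, 0, 0.3, 0)$p_value, 1)

  # Welch policy needs df and uses the t reference
  expect_error(compare_conditions(0.3, 0.1, 0.5, 0.1, df_policy = "welch"),
               "df")
  wt <- compare_conditions(0.3, 0.1, 0.5, 0.1, df_policy = "welch", df = 4)
  expect_gt(wt$p_value, compare_conditions(0.3, 0.1, 0.5, 0.1)$p_value)
})

test_that("bootstrap sigma approximates the Fisher-information rate for K=1", {
  tau <- 5
  n <- 500
  d <- simulate_dwells(mixture_model(1, tau), obs_window(0.1, 1e9),
                       sim_config(n, seed = 71))
  # raw draws below t_min are discarded, so slightly fewer than n remain
  n_kept <- length(d$durations)
  b <- bootstrap_fit(d, K = 1, n_boot = 250, seed = 5, n_restarts = 0)
  sig_tau <- b$summary$sigma[b$summary$parameter == "tau1"]
  expect_equal(sig_tau, tau / sqrt(n_kept), tolerance = 0.30)
  expect_true(b$valid)
})

test_that("resampling a constant gives zero bootstrap sigma", {
  d <- dwell_dataset(rep(2, 50), obs_window(0.1, 1e9))
  b <- bootstrap_fit(d, K = 1, n_boot = 30, seed = 2, n_restarts = 0)
  expect_equal(b$summary$sigma[b$summary$parameter == "tau1"], 0)
})

test_that("bootstrap sigma shrinks like one over root n", {
  sig_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      d <- simulate_dwells(mixture_model(1, 5), obs_window(0.1, 1e9),
                           sim_config(n, seed = 7000 + s))
      b <- bootstrap_fit(d, K = 1, n_boot = 150, seed = s, n_restarts = 0)
      b$summary$sigma[b$summary$parameter == "tau1"]
    }, numeric(1)))
  }
  seeds <- 1:8
  s250 <- sig_at(250, seeds)
  s1000 <- sig_at(1000, seeds)
  s4000 <- sig_at(4000, seeds)
  expect_equal(s250 / s1000, 2, tolerance = 0.25)
  expect_equal(s1000 / s4000, 2, tolerance = 0.25)
})

test_that("stable-fraction sigma on a Crc-like dataset has the reported scale", {
  d <- simulate_dwells(mixture_model(c(0.30, 0.70), c(2, 60)),
                       standard_window(), sim_config(3000, seed = 81))
  b <- bootstrap_fit(d, K = 2, n_boot = 200, seed = 8, n_restarts = 1)
  sig_along <- b$summary$sigma[b$summary$parameter == "a2"]
  # same order of magnitude as the study's reported 0.04 (its event count
  # is unknown, so only the scale is comparable)
  expect_gt(sig_along, 0.004)
  expect_lt(sig_along, 0.4)
  expect_true(b$valid)
})

test_that("propagated residual sigma ignores the amplitude covariance", {
  # the propagation formula assumes independent a1, a2; the direct bootstrap
  # sigma of a3 = 1 - a1 - a2 includes their covariance.  The exact variance
  # identity var(a3) = var(a1) + var(a2) + 2 cov(a1, a2) quantifies the
  # approximation on correlated fits.
  d <- simulate_dwells(mixture_model(c(0.81, 0.05, 0.14), c(0.4, 2, 60)),
                       standard_window(), sim_config(1500, seed = 91))
  base <- fit_mixture(d, K = 3, n_starts = 12, seed = 9)
  b <- bootstrap_fit(d, base_fit = base, n_boot = 60, seed = 9, n_restarts = 1)
  a1 <- b$samples[, "a1"]
  a2 <- b$samples[, "a2"]
  a3 <- b$samples[, "a3"]
  expect_equal(stats::sd(a3), stats::sd(1 - a1 - a2), tolerance = 1e-9)
  prop <- propagate_residual_sigma(stats::sd(a1), stats::sd(a2))
  expect_equal(stats::var(a3), prop^2 + 2 * stats::cov(a1, a2),
               tolerance = 1e-8)
  # the amplitudes of a simplex-constrained fit are correlated, so the two
  # sigmas genuinely differ here
  expect_gt(abs(stats::cor(a1, a2)), 0.01)
  expect_false(isTRUE(all.equal(prop, stats::sd(a3), tolerance = 1e-3)))
})

test_that("molecule-level block bootstrap runs and reports sigma", {
  d <- simulate_dwells(mixture_model(1, 5), obs_window(0.1, 1e6),
                       sim_config(400, seed = 14))
  b <- bootstrap_fit(d, K = 1, n_boot = 50, seed = 3, n_restarts = 0,
                     unit = "molecule")
  expect_gt(b$summary$sigma[b$summary$parameter == "tau1"], 0)
})
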