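test_that("single-exponential dwells have the analytic quantized mean", {
  tau <- 5
  fi <- 0.1
  w <- obs_window(0.1, 10000)
  d <- simulate_dwells(mixture_model(1, tau), w,
                       sim_config(20000, frame_interval = fi, seed = 101))
  # with left truncation at one frame and round-up quantization the mean is
  # fi + fi / (1 - exp(-fi/tau)); derived from memorylessness of the
  # exponential, independently of the simulator
  expected <- fi + fi / (1 - exp(-fi / tau))
  expect_equal(mean(d$durations), expected, tolerance = 0.02)
  # ... which itself sits within ~3.5% of the generating lifetime
  expect_equal(mean(d$durations), tau, tolerance = 0.04)
})

test_that("a degenerate mixture weight reproduces the single-exponential law", {
  w <- obs_window(0.1, 180)
  cfg <- sim_config(4000, seed = 7)
  d_mix <- simulate_dwells(mixture_model(c(1, 0), c(2, 60)), w, cfg)
  d_one <- simulate_dwells(mixture_model(1, 2), w, cfg)
  ks <- suppressWarnings(stats::ks.test(d_mix$durations, d_one$durations))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated dwells follow the analytic truncated mixture CDF", {
  # fine frame interval so quantization does not distort the comparison
  # against the continuous law
  w <- obs_window(0.1, 180)
  n <- 10000
  d <- simulate_dwells(two_state_model(), w,
                       sim_config(n, frame_interval = 0.001, seed = 202))
  D <- ks_distance(d$durations,
                   function(t) oracle_cdf(t, c(0.56, 0.44), c(2, 60), 0.1, 180))
  n_kept <- length(d$durations)
  expect_lt(D, 1.628 / sqrt(n_kept))  # KS critical distance at alpha = 0.01
})

test_that("photobleaching acts as a competing exponential (rate addition)", {
  tau <- 60
  tau_b <- 173
  w <- obs_window(0.1, 10000)
  d <- simulate_dwells(mixture_model(1, tau), w,
                       sim_config(10000, bleach_lifetime = tau_b, seed = 33))
  f <- fit_mixture(d, K = 1, n_starts = 8, seed = 1)
  expect_equal(f$model$lifetimes, 1 / (1 / tau + 1 / tau_b), tolerance = 0.05)
})

test_that("discard fraction below t_min matches the mixture survival", {
  m <- two_state_model()
  w <- obs_window(0.5, 180)
  n <- 20000
  d <- simulate_dwells(m, w, sim_config(n, seed = 55))
  p_short <- 1 - (0.56 * exp(-0.5 / 2) + 0.44 * exp(-0.5 / 60))
  frac <- d$n_discarded_short / n
  expect_lt(abs(frac - p_short), 4 * sqrt(p_short * (1 - p_short) / n))
})

test_that("same seed gives bit-identical datasets", {
  w <- standard_window()
  d1 <- simulate_dwells(two_state_model(), w, sim_config(500, seed = 42))
  d2 <- simulate_dwells(two_state_model(), w, sim_config(500, seed = 42))
  expect_identical(d1, d2)
  d3 <- simulate_dwells(two_state_model(), w, sim_config(500, seed = 43))
  expect_false(identical(d1$durations, d3$durations))
})

test_that("window filters report which filter removed everything", {
  expect_error(
    simulate_dwells(mixture_model(1, 0.001), obs_window(0.1, 180),
                    sim_config(50, seed = 1)),
    "minimum resolvable interval")
  expect_error(
    simulate_dwells(mixture_model(1, 5000), obs_window(0.1, 1),
                    sim_config(20, seed = 1)),
    "t_max")
})

test_that("cap_at_window retains right-censored events at t_max", {
  m <- mixture_model(1, 500)
  w <- obs_window(0.1, 10)
  d <- simulate_dwells(m, w, sim_config(1000, seed = 9,
                                        censoring_policy = "cap_at_window"))
  expect_identical(d$n_discarded_long, 0L)
  expect_true(any(d$durations == 10))
  expect_true(all(d$durations <= 10))
})

test_that("simulated decay series reproduce the textbook checkpoints", {
  # first order, half-life 1 min: 50% at t = 1
  s1 <- normalize_to_reference(simulate_decay(1, c(0, 1), "first_order"))
  expect_equal(s1$percent_remaining[2], 50, tolerance = 1e-12)
  # linear, half-life 10 min: 50% at t = 10
  s2 <- normalize_to_reference(simulate_decay(10, c(0, 5, 10), "linear"))
  expect_equal(s2$percent_remaining[3], 50, tolerance = 1e-12)
  # first order, half-life 1.7 min: 12.5% after three half-lives
  s3 <- normalize_to_reference(simulate_decay(1.7, c(0, 5.1), "first_order"))
  expect_equal(s3$percent_remaining[2], 12.5, tolerance = 1e-9)
  expect_error(simulate_decay(1, c(1, 2), "first_order"), "start at 0")
})

test_that("trace simulation plants events where scheduled", {
  cfg <- sim_config(1, frame_interval = 0.1, seed = 5)
  # one event covering frames 10-19 (0-based), i.e. 1.0-2.0 s
  ts <- simulate_traces(list(data.frame(start_s = 1, end_s = 2)),
                        cfg, snr = 100, n_frames = 40)
  above <- ts$traces[[1]] > 100 + 500  # baseline + half the amplitude
  expect_identical(which(above), 11:20)

  # empty schedule: pure noise, nothing near the event amplitude
  ts0 <- simulate_traces(list(data.frame(start_s = numeric(0),
                                         end_s = numeric(0))),
                         cfg, snr = 10, n_frames = 200)
  expect_true(all(ts0$traces[[1]] < 100 + 500))

  expect_error(
    simulate_traces(list(data.frame(start_s = c(1, 1.5), end_s = c(2, 3))),
                    cfg, snr = 10, n_frames = 40),
    "overlapping")
  expect_error(
    simulate_traces(list(data.frame(start_s = 1, end_s = 100)),
                    cfg, snr = 10, n_frames = 40),
    "outside the recording")
})
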