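test_that("reference normalization behaves like the ratio method", {
  # constant target and reference: flat 100%
  s <- normalize_to_reference(decay_series(0:3, rep(40, 4), rep(800, 4)))
  expect_equal(s$percent_remaining, rep(100, 4))
  expect_false(attr(s, "non_decaying"))

  # target halves while the reference is constant
  s2 <- normalize_to_reference(decay_series(c(0, 1), c(40, 20), c(800, 800)))
  expect_equal(s2$percent_remaining, c(100, 50))

  # reference doubling with constant target: apparent increase, flagged
  s3 <- normalize_to_reference(decay_series(c(0, 1), c(40, 40), c(800, 400)))
  expect_equal(s3$percent_remaining, c(100, 200))
  expect_true(attr(s3, "non_decaying"))

  # invariance to rescaling either signal by positive constants
  a <- normalize_to_reference(decay_series(0:4, c(50, 30, 20, 12, 8),
                                           c(900, 880, 910, 905, 895)))
  b <- normalize_to_reference(decay_series(0:4, 7.3 * c(50, 30, 20, 12, 8),
                                           0.11 * c(900, 880, 910, 905, 895)))
  expect_equal(a$percent_remaining, b$percent_remaining, tolerance = 1e-12)
})

test_that("first-order estimator recovers exponential half-lives exactly", {
  # unit half-life sanity
  r1 <- fit_first_order(simulate_decay(1, 0:5, "first_order"))
  expect_equal(r1$half_life, 1, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)

  # the wild-type condition: 1.7 min recovered to 1e-6 from a noiseless series
  r2 <- fit_first_order(simulate_decay(1.7, 0:8, "first_order"))
  expect_equal(r2$half_life, 1.7, tolerance = 1e-6)

  # exactness holds across the plausible half-life range
  for (hl in c(0.5, 3, 12, 60)) {
    r <- fit_first_order(simulate_decay(hl, seq(0, 4 * hl, length.out = 6),
                                        "first_order"))
    expect_equal(r$half_life, hl, tolerance = 1e-9)
  }
})

test_that("first-order estimator equals the closed-form log-linear OLS", {
  s <- normalize_to_reference(
    simulate_decay(1.7, 0:8, "first_order", noise_sd = 5, seed = 123))
  r <- fit_first_order(s)
  # independent OLS of log(percent) on time
  x <- s$time_min
  y <- log(s$percent_remaining)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- slope^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  expect_equal(r$rate, -slope, tolerance = 1e-9)
  expect_equal(r$half_life, log(2) / (-slope), tolerance = 1e-9)
  expect_equal(r$r_squared, r2, tolerance = 1e-9)
})

test_that("linear-trendline estimator recovers linear half-lives", {
  # (100, 75, 50) at t = 0, 1, 2: slope 25 %/min, half-life 2 min
  s <- normalize_to_reference(decay_series(0:2, c(100, 75, 50), rep(1, 3)))
  r <- fit_linear(s)
  expect_equal(r$rate, 25, tolerance = 1e-12)
  expect_equal(r$half_life, 2, tolerance = 1e-12)

  # the crc-deletion condition: 10.4 min recovered to 1e-6
  r2 <- fit_linear(simulate_decay(10.4, 0:8, "linear"))
  expect_equal(r2$half_life, 10.4, tolerance = 1e-6)

  # flat series: no decay, no half-life
  flat <- fit_linear(normalize_to_reference(
    decay_series(0:4, rep(30, 5), rep(600, 5))))
  expect_true(flat$no_decay)
  expect_true(is.na(flat$half_life))
})

test_that("estimator selection prefers first-order only when it fits well", {
  # clean exponential: first-order wins
  fo <- choose_method(simulate_decay(1.7, 0:8, "first_order"))
  expect_identical(fo$method, "first_order")
  expect_equal(fo$half_life, 1.7, tolerance = 1e-6)

  # clean linear decay spanning 100% down to ~4%: the log-scale curvature
  # drags the exponential-trendline R^2 below the 0.90 adequacy bar
  s_lin <- simulate_decay(10.4, seq(0, 20, by = 2), "linear")
  sel <- choose_method(s_lin)
  expect_identical(sel$method, "linear")
  expect_lt(sel$candidates$first_order$r_squared, 0.90)
  expect_equal(sel$half_life, 10.4, tolerance = 1e-6)

  # too few points
  expect_error(choose_method(normalize_to_reference(
    decay_series(c(0, 1), c(10, 5), c(2, 2)))), "insufficient points")
})

test_that("the stability contrast between conditions exceeds six-fold", {
  wt <- choose_method(simulate_decay(1.7, 0:8, "first_order"))
  mut <- choose_method(simulate_decay(10.4, 0:8, "linear"))
  expect_gt(mut$half_life / wt$half_life, 6)
})

test_that("first-order fit rejects non-positive percentages by name", {
  s <- normalize_to_reference(decay_series(0:3, c(40, 20, 10, 5), rep(1, 4)))
  s$percent_remaining[3] <- -1
  expect_error(fit_first_order(s), "time point\\(s\\) 2")
})
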