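test_that("K=1 maximum likelihood matches a dense grid search", {
  w <- obs_window(0.1, 1e6)
  d <- simulate_dwells(mixture_model(1, 5), w, sim_config(5000, seed = 12))
  f <- fit_mixture(d, K = 1, n_starts = 8, seed = 1)
  tau_grid <- oracle_grid_mle_k1(d$durations, 0.1, 1e6)
  expect_equal(f$model$lifetimes, tau_grid, tolerance = 0.03)
  expect_true(f$converged)
})

test_that("two-state parameters are recovered from the standard window", {
  d <- simulate_dwells(two_state_model(), standard_window(),
                       sim_config(5000, seed = 21))
  f <- fit_mixture(d, K = 2, n_starts = 20, seed = 2)
  expect_equal(f$model$lifetimes[1], 2, tolerance = 0.15)
  expect_equal(f$model$lifetimes[2], 60, tolerance = 0.15)
  expect_lt(abs(f$model$weights[1] - 0.56), 0.05)
  expect_lt(abs(f$model$weights[2] - 0.44), 0.05)
  expect_true(all(diff(f$model$lifetimes) > 0))  # ascending label order
})

test_that("the fitted optimum is at least as likely as the truth", {
  w <- standard_window()
  m <- two_state_model()
  for (s in 1:5) {
    d <- simulate_dwells(m, w, sim_config(800, seed = 300 + s))
    f <- fit_mixture(d, K = 2, n_starts = 10, seed = s)
    ll_true <- -neg_log_likelihood(d, m)
    expect_gte(f$log_likelihood, ll_true - 1e-6)
  }
})

test_that("estimates tighten as the sample grows", {
  w <- standard_window()
  m <- two_state_model()
  rmse <- function(n, seeds) {
    errs <- vapply(seeds, function(s) {
      d <- simulate_dwells(m, w, sim_config(n, seed = 4000 + s))
      f <- fit_mixture(d, K = 2, n_starts = 8, seed = s)
      f$model$weights[2] - 0.44
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(5000, 1:8), rmse(500, 1:8))
})

test_that("the event-count guard refuses underpowered fits", {
  d <- simulate_dwells(mixture_model(1, 5), obs_window(0.1, 1e4),
                       sim_config(25, seed = 2))
  expect_error(fit_mixture(d, K = 3), "too few events")
})

test_that("BIC selects the generating number of components", {
  w <- standard_window()

  # overfit candidates legitimately trigger the resolvable-components
  # warning while being rejected by BIC, hence the suppression
  d1 <- simulate_dwells(mixture_model(1, 5), w, sim_config(5000, seed = 61))
  s1 <- suppressWarnings(select_K(d1, candidate_Ks = 1:3, n_starts = 10,
                                  seed = 1))
  expect_identical(s1$K, 1L)

  d2 <- simulate_dwells(two_state_model(), w, sim_config(5000, seed = 62))
  s2 <- suppressWarnings(select_K(d2, candidate_Ks = 1:3, n_starts = 10,
                                  seed = 1))
  expect_identical(s2$K, 2L)
  # likelihood-ratio sanity check on the implementation's own table:
  # the K=2 improvement over K=1 must dwarf the chi-square bar
  tab <- s2$bic_table
  lr <- 2 * (tab$log_likelihood[tab$K == 2] - tab$log_likelihood[tab$K == 1])
  expect_gt(lr, stats::qchisq(0.99, df = 2))

  d3 <- simulate_dwells(mixture_model(c(0.81, 0.05, 0.14), c(0.2, 2, 60)),
                        w, sim_config(10000, seed = 63))
  s3 <- select_K(d3, candidate_Ks = 1:3, n_starts = 12, seed = 1)
  expect_identical(s3$K, 3L)
  lr32 <- 2 * diff(s3$bic_table$log_likelihood[2:3])
  expect_gt(lr32, stats::qchisq(0.99, df = 2))

  expect_error(select_K(d1, candidate_Ks = c(1, 5)), "subset of 1:4")
})

test_that("fit failures for one K do not abort the others", {
  # 35 events: enough for K=1..3 guards except K=4 (needs 40)
  d <- simulate_dwells(mixture_model(1, 5), obs_window(0.1, 1e4),
                       sim_config(40, seed = 5))
  d$durations <- d$durations[1:35]
  d$molecule_id <- d$molecule_id[1:35]
  d$start_s <- d$start_s[1:35]
  s <- select_K(d, candidate_Ks = c(1, 4), n_starts = 6, seed = 1)
  expect_identical(s$K, 1L)
  expect_match(s$bic_table$error[s$bic_table$K == 4], "too few events")
})

test_that("fits are deterministic given data and seed", {
  d <- simulate_dwells(two_state_model(), standard_window(),
                       sim_config(1000, seed = 9))
  f1 <- fit_mixture(d, K = 2, n_starts = 6, seed = 3)
  f2 <- fit_mixture(d, K = 2, n_starts = 6, seed = 3)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})
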