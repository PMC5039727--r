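test_that("the acceptance curve is a monotone logistic with midpoint 0.5", {
  fit <- logistic_acceptance(15.52, 0.21)
  expect_equal(acceptance_curve(fit, 0.21), 0.5)
  expect_equal(acceptance_curve(fit, 0.5),
               stats::plogis(15.52 * (0.5 - 0.21)), tolerance = 1e-12)
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(acceptance_curve(fit, x)) > 0))
  expect_true(all(acceptance_curve(fit, x) > 0 & acceptance_curve(fit, x) < 1))
  expect_error(logistic_acceptance(-3, 0.2))
  expect_error(acceptance_curve(fit, 1.5), "\\[0, 1\\]")
})

test_that("fitting recovers generating parameters from noiseless and binomial data", {
  # noiseless rates on the empirical bin range recover (k, X0) near-exactly
  bins <- seq(0.05, 0.5, by = 0.05)
  noiseless <- tibble::tibble(
    offer_bin = bins,
    acceptance_rate = logistic_f(bins, 10, 0.3)
  )
  fit <- fit_acceptance_curve(noiseless, augment = FALSE)
  expect_lt(abs(fit$k - 10), 1e-3)
  expect_lt(abs(fit$X0 - 0.3), 1e-3)

  # binomial sampling, 100 seeds, n = 500 per bin: X0 is well identified
  err <- vapply(1:100, function(s) {
    d <- withr::with_seed(s, simulate_acceptance_data(15.52, 0.21,
                                                      n_per_bin = 500))
    abs(fit_acceptance_curve(d)$X0 - 0.21)
  }, numeric(1))
  expect_lt(median(err), 0.02)

  # RMSE of (k, X0) shrinks as the per-bin sample grows
  rmse <- function(n) {
    e <- vapply(1:40, function(s) {
      d <- withr::with_seed(1000 + s,
                            simulate_acceptance_data(15.52, 0.21,
                                                     n_per_bin = n))
      f <- fit_acceptance_curve(d)
      (f$X0 - 0.21)^2
    }, numeric(1))
    sqrt(mean(e))
  }
  expect_lt(rmse(4000), 0.6 * rmse(250))
})

test_that("saturation augmentation is benign when the data already saturate", {
  d <- withr::with_seed(3, simulate_acceptance_data(
    15.52, 0.21, bins = seq(0.05, 0.95, by = 0.05), n_per_bin = 2000))
  with_aug <- fit_acceptance_curve(d, augment = TRUE)
  without <- fit_acceptance_curve(d, augment = FALSE)
  expect_lt(abs(with_aug$k - without$k) / without$k, 0.05)
  expect_lt(abs(with_aug$X0 - without$X0), 0.01)
})

test_that("fit failures carry diagnostics", {
  flat <- tibble::tibble(offer_bin = seq(0.1, 0.5, 0.1),
                         acceptance_rate = rep(0.5, 5))
  expect_error(fit_acceptance_curve(flat, augment = FALSE), "degenerate")
  expect_error(
    fit_acceptance_curve(tibble::tibble(offer_bin = c(0.1, 0.2),
                                        acceptance_rate = c(0.1, 0.9)),
                         augment = FALSE),
    "3 distinct")
})

test_that("demand threshold has the right limits and matches the quadrature oracle", {
  # near-flat curve: accepted mass is uniform, median 0.5
  expect_equal(demand_threshold(logistic_acceptance(1e-4, 0.5)), 0.5,
               tolerance = 1e-3)
  # step at 0.5: accepted mass uniform on [0.5, 1], median 0.75
  expect_equal(demand_threshold(logistic_acceptance(1000, 0.5)), 0.75,
               tolerance = 1e-3)
  # monotone increasing in X0 at fixed k
  d_seq <- vapply(seq(0.1, 0.9, by = 0.1), function(x0) {
    demand_threshold(logistic_acceptance(8, x0))
  }, numeric(1))
  expect_true(all(diff(d_seq) > 0))
  # random curves against the Riemann + interpolation oracle
  set.seed(77)
  for (i in 1:100) {
    k <- runif(1, 0.5, 50); x0 <- runif(1, 0.05, 0.95)
    expect_equal(demand_threshold(logistic_acceptance(k, x0)),
                 oracle_demand_threshold(k, x0), tolerance = 1e-5)
  }
})

test_that("the optimal offer maximises expected payoff and matches grid search", {
  # flat acceptance: payoff 0.5 * (1 - offer) is maximised at 0
  expect_lt(optimal_offer(logistic_acceptance(1e-4, 0.5)), 1e-4)
  # steep acceptance at 0.5: the maximiser sits just above the step, where
  # the curve has finished rising (O(log(k)/k) above 0.5 for finite k)
  expect_lt(abs(optimal_offer(logistic_acceptance(2000, 0.5)) - 0.5), 0.01)
  expect_equal(expected_payoff(logistic_acceptance(15.52, 0.21), 1), 0)
  expect_equal(expected_payoff(logistic_acceptance(1e-6, 0.5), c(0.2, 0.6)),
               0.5 * c(0.8, 0.4), tolerance = 1e-4)
  set.seed(88)
  for (i in 1:100) {
    k <- runif(1, 2, 60); x0 <- runif(1, 0.05, 0.95)
    fit <- logistic_acceptance(k, x0)
    mine <- optimal_offer(fit)
    grid <- oracle_optimal_offer(k, x0)
    # same payoff to numerical precision, same location up to grid resolution
    expect_lt(expected_payoff(fit, grid) - expected_payoff(fit, mine), 1e-9)
    expect_lt(abs(mine - grid), 2e-4)
  }
})

test_that("simulated acceptance tables are valid, reproducible binomial draws", {
  d1 <- withr::with_seed(5, simulate_acceptance_data(15.52, 0.21))
  d2 <- withr::with_seed(5, simulate_acceptance_data(15.52, 0.21))
  expect_identical(d1, d2)
  expect_true(all(d1$n_accepted >= 0 & d1$n_accepted <= d1$n_total))
  # large-sample rates sit inside 3-sigma binomial bands of the true curve
  big <- withr::with_seed(6, simulate_acceptance_data(15.52, 0.21,
                                                      n_per_bin = 1e5))
  p <- logistic_f(big$offer_bin, 15.52, 0.21)
  band <- 3 * sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(big$n_accepted / big$n_total - p) <= band + 1e-12))
})

test_that("acceptance tables round-trip through CSV in both forms", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- withr::with_seed(2, simulate_acceptance_data(10, 0.3, n_per_bin = 50))
  readr::write_csv(d, path)
  expect_equal(as.data.frame(read_acceptance_data(path)), as.data.frame(d))
  rate_form <- tibble::tibble(offer_bin = c(0.1, 0.3),
                              acceptance_rate = c(0.2, 0.9))
  readr::write_csv(rate_form, path)
  expect_equal(as.data.frame(read_acceptance_data(path)),
               as.data.frame(rate_form))
  readr::write_csv(tibble::tibble(x = 1), path)
  expect_error(read_acceptance_data(path), "offer_bin")
})

test_that("the inferred human strategy vector is generous, demanding, and unfair", {
  labels <- classify_strategy(0.4, 0.61)
  expect_true(labels$generous)
  expect_true(labels$demanding)
  expect_true(labels$unfair)
  nash <- classify_strategy(0.001, 0.001)
  expect_false(nash$generous)
  expect_false(nash$demanding)
  expect_false(nash$unfair)
})

test_that("tidy and glance summarise a fit", {
  fit <- logistic_acceptance(15.52, 0.21, residual_sum_of_squares = 0.01)
  td <- tidy(fit)
  expect_equal(td$term, c("k", "X0"))
  expect_equal(td$estimate, c(15.52, 0.21))
  g <- glance(fit)
  expect_equal(g$demand, demand_threshold(fit))
  expect_equal(g$optimal_offer, optimal_offer(fit))
  expect_s3_class(autoplot(fit), "ggplot")
})
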