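test_that("correlation metric matches the textbook formula", {
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(metric_cc(x, x), 1)
  expect_equal(metric_cc(-x, x), -1)
  p <- c(1, 2, 3, 5); t <- c(1, 2, 3, 4)
  hand <- sum((p - mean(p)) * (t - mean(t))) /
    sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))
  expect_equal(metric_cc(p, t), hand)
  # NA-aligned rows are dropped, zero-variance channels excluded
  pm <- cbind(c(NA, p), c(NA, rep(1, 4)))
  tm <- cbind(c(NA, t), c(NA, rnorm(4)))
  expect_warning(v <- metric_cc(pm, tm), "zero-variance")
  expect_equal(v, hand)
  expect_error(metric_cc(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("R-squared metric matches its definition", {
  t <- rnorm(50)
  expect_equal(metric_r2(t, t), 1)
  expect_equal(metric_r2(rep(mean(t), 50), t), 0, tolerance = 1e-12)
  p <- t + 0.5
  expect_equal(metric_r2(p, t), 1 - sum(0.25 * 50) / sum((t - mean(t))^2))
})

test_that("eigenvalue error is an assignment-invariant pseudometric", {
  ev <- c(0.9 + 0.1i, 0.9 - 0.1i, 0.5 + 0i)
  expect_equal(eigenvalue_error(ev, ev), 0)
  expect_equal(eigenvalue_error(ev, rev(ev)), 0)
  # hand-checked 2-element case: optimal matching distance (0.1 + 0)/2,
  # normalized by mean true modulus 0.7
  expect_equal(eigenvalue_error(c(0.9 + 0i, 0.5 + 0i),
                                c(0.8 + 0i, 0.5 + 0i)),
               (0.1 / 2) / 0.7)
  # symmetry up to normalization base; cardinality mismatch errors
  expect_error(eigenvalue_error(ev, ev[1:2]), "equal cardinality")
  # greedy + 2-opt path for larger sets agrees with brute force at n = 8
  set.seed(2)
  a <- complex(real = rnorm(8), imaginary = rnorm(8))
  b <- a[sample(8)] + complex(real = rnorm(8, sd = 0.01),
                              imaginary = rnorm(8, sd = 0.01))
  expect_lt(eigenvalue_error(a, b), 0.02)
})

test_that("cross-validation partitions, aggregates and reproduces", {
  sim <- tiny_sim(seed = 5, T = 900L)
  rep1 <- cross_validate(sim$ds, n1 = 2L, config = quick_config())
  rep2 <- cross_validate(sim$ds, n1 = 2L, config = quick_config())
  expect_equal(rep1$fold_metrics, rep2$fold_metrics, tolerance = 1e-12)
  expect_equal(sort(unique(rep1$fold_metrics$fold)), c(1L, 2L))
  # aggregation arithmetic equals a direct recomputation
  m <- rep1$fold_metrics
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "cc_z"], mean(m$cc_z))
  expect_equal(s$sem[s$metric == "cc_z"], sd(m$cc_z) / sqrt(nrow(m)))
  pooled <- pool_reports(list(rep1, rep2))
  expect_equal(max(pooled$summary$n_runs), 4L)
  expect_error(cross_validate(sim$ds, n1 = 2L,
                              config = quick_config(horizons = 1:450)),
               "horizon")
})

test_that("forecast curve at m = 1 equals the standard one-step metrics", {
  sim <- tiny_sim(seed = 9, T = 900L)
  sp <- braid:::split_folds(sim$ds, 2)
  fit <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                   config = quick_config())
  fc <- forecast_curve(fit, sp$test$y, sp$test$u, sp$test$z,
                       horizons = c(1L, 2L, 4L))
  pr <- predict(fit, sp$test$y, sp$test$u, horizons = 1L)
  expect_equal(fc$cc_z[1], metric_cc(pr$z[[1]], sp$test$z))
  expect_equal(fc$r2_y[1], metric_r2(pr$y[[1]], sp$test$y))
  expect_equal(fc$horizon, c(1L, 2L, 4L))
})

test_that("swapping test data into training changes the result (leakage canary)", {
  sim <- tiny_sim(seed = 13, T = 900L)
  sp <- braid:::split_folds(sim$ds, 2)
  fit_clean <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                         config = quick_config())
  fit_leaky <- braid_fit(sp$test$y, sp$test$z, sp$test$u, n1 = 2L,
                         config = quick_config())
  pr_clean <- predict(fit_clean, sp$test$y, sp$test$u, horizons = 1L)
  pr_leaky <- predict(fit_leaky, sp$test$y, sp$test$u, horizons = 1L)
  expect_false(isTRUE(all.equal(metric_cc(pr_clean$z[[1]], sp$test$z),
                                metric_cc(pr_leaky$z[[1]], sp$test$z))))
})
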