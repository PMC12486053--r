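test_that("multi-horizon loss is the weighted sum of aligned MSEs", {
  T <- 20L
  z <- matrix(rnorm(T * 2), T, 2)
  aligned <- list(z)  # perfect 1-step predictions, aligned layout
  expect_equal(loss_mstep(aligned, z, horizons = 1L), 0)
  off <- z + 0.3
  expect_equal(loss_mstep(list(off), z, horizons = 1L), 0.09,
               tolerance = 1e-12)
  # two horizons with hand-computed MSEs sum under unit weights
  p1 <- z[2:T, , drop = FALSE] + sqrt(0.2)     # rows k predict k+1
  p2 <- z[3:T, , drop = FALSE] + sqrt(0.3)
  expect_equal(loss_mstep(list(p1, p2), z, horizons = c(1L, 2L)),
               0.5, tolerance = 1e-12)
  expect_equal(loss_mstep(list(p1, p2), z, horizons = c(1L, 2L),
                          weights = c(2, 1)), 0.7, tolerance = 1e-12)
  expect_error(loss_mstep(list(p1[1:3, ]), z, horizons = 1L),
               "incompatible length")
})

test_that("configuration enforces variant constraints", {
  cfg <- braid_config(variant = "linear_braid",
                      nonlinearity = list(Cz = "nonlinear"))
  expect_equal(cfg$nonlinearity$Cz, "linear")
  expect_error(braid_config(horizons = 0L), ">= 1")
  expect_error(braid_config(hweights = c(1, 2)), "match horizons")
})

test_that("behavior preprocessor captures neural-encoded behavior only", {
  set.seed(21)
  T <- 1500L
  y <- matrix(rnorm(T * 4), T, 4)
  # memoryless linear behavior: fully recoverable from y alone
  z <- y %*% matrix(c(1, 0.5, -1, 0.2, 0, 1, 1, -0.5), 4, 2)
  pp <- preprocess_behavior(y, z, quick_config(), n1 = 2L)
  expect_gt(metric_cc(pp$z_pre, z), 0.99)
  # shuffling y in time destroys the dependence for a dynamic target
  sys <- generate_random_system(seed = 14, nonlinearity = "none")
  ds <- simulate_system(sys, T = 1500, seed = 14)
  set.seed(123)
  pp2 <- preprocess_behavior(ds$y[sample(nrow(ds$y)), ], ds$z,
                             quick_config(), n1 = 2L)
  expect_lt(abs(metric_cc(pp2$z_pre, ds$z)), 0.15)
})

test_that("degenerate behavior channels warn and pass through", {
  set.seed(3)
  y <- matrix(rnorm(600 * 3), 600, 3)
  z <- cbind(y[, 1], 2)   # second channel constant
  expect_warning(pp <- preprocess_behavior(y, z, quick_config(), n1 = 1L),
                 "zero-variance")
  expect_equal(unname(pp$z_pre[, 2]), rep(2, 600), tolerance = 0.05)
})

test_that("later stages leave stage-1 weights bit-identical", {
  sim <- tiny_sim(seed = 4)
  sp <- braid:::split_folds(sim$ds, 2)
  cfg <- quick_config()
  f1 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                  config = cfg)
  f12 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L, n2 = 2L,
                   config = cfg)
  expect_identical(f1$sections$s1$sec$A$layers,
                   f12$sections$s1$sec$A$layers)
  expect_identical(f1$sections$s1$sec$K$layers,
                   f12$sections$s1$sec$K$layers)
  expect_identical(f1$sections$s1$Cz$layers, f12$sections$s1$Cz$layers)
})

test_that("stage-2 states lift neural prediction on systems with neural-only dims", {
  sys <- generate_random_system(seed = 16, n_x = 4L, nonlinearity = "none",
                                z_subspace_dim = 2L,
                                process_noise_frac = 0.3)
  ds <- simulate_system(sys, T = 4000, seed = 16)
  sp <- braid:::split_folds(ds, 2)
  cfg <- quick_config(epochs = 60L)
  f1 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L, config = cfg)
  f12 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L, n2 = 2L,
                   config = cfg)
  cc1 <- metric_cc(predict(f1, sp$test$y, sp$test$u)$y[[1]], sp$test$y)
  cc12 <- metric_cc(predict(f12, sp$test$y, sp$test$u)$y[[1]], sp$test$y)
  expect_gt(cc12, cc1 + 0.03)
})

test_that("stage 3 requires measured inputs and adds only behavior terms", {
  sim <- tiny_sim(seed = 6)
  sp <- braid:::split_folds(sim$ds, 2)
  expect_error(braid_fit(sp$train$y, sp$train$z, NULL, n1 = 2L, n3 = 2L,
                         config = quick_config()), "n_u")
  f3 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L, n3 = 2L,
                  config = quick_config())
  expect_null(f3$sections$s3$Cy)
  expect_identical(f3$sections$s3$inputs, "u")
  # the section-3 encoder consumes the input dimension only, never y
  expect_equal(f3$sections$s3$sec$K$d_in, ncol(sp$train$u))
})

test_that("nonlinearity selection is an argmax with simpler-first ties", {
  sim <- tiny_sim(seed = 8, T = 1000L)
  sp <- braid:::split_folds(sim$ds, 2)
  sel <- auto_select_nonlinearity(sp$train$y, sp$train$z, sp$train$u,
                                  n1 = 2L, config = quick_config(),
                                  maps_grid = "Cz")
  expect_equal(nrow(sel$scores), 2L)
  # candidates are ordered simpler-first and the winner attains the max
  expect_equal(sel$scores$n_nonlinear, c(0L, 1L))
  best <- max(sel$scores$cc_z, na.rm = TRUE)
  expect_equal(
    sel$scores$cc_z[match(sel$assignment$Cz, sel$scores$Cz)], best)
  expect_s3_class(sel$model, "braid_model")
})

test_that("fits are exactly reproducible under a fixed seed", {
  sim <- tiny_sim(seed = 10)
  sp <- braid:::split_folds(sim$ds, 2)
  f1 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                  config = quick_config(nonlinearity = list(Cz = "nonlinear")))
  f2 <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                  config = quick_config(nonlinearity = list(Cz = "nonlinear")))
  p1 <- predict(f1, sp$test$y, sp$test$u)
  p2 <- predict(f2, sp$test$y, sp$test$u)
  expect_identical(p1$z[[1]], p2$z[[1]])
})

test_that("the no-input ablation consumes no input anywhere", {
  sim <- tiny_sim(seed = 12)
  sp <- braid:::split_folds(sim$ds, 2)
  f <- braid_fit(sp$train$y, sp$train$z, sp$train$u, n1 = 2L,
                 config = quick_config(variant = "no_input_ablation"))
  expect_null(f$sections$s1$sec$Kfw)
  pr1 <- predict(f, sp$test$y, sp$test$u, horizons = 2L)
  pr2 <- predict(f, sp$test$y, sp$test$u * 5, horizons = 2L)
  expect_identical(pr1$z[[1]], pr2$z[[1]])
})
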