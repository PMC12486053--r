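test_that("transform_spec enforces the linear/nonlinear contract", {
  sp <- transform_spec("linear")
  expect_equal(sp$hidden_layers, 0L)
  expect_error(transform_spec("nonlinear", hidden_layers = 0L),
               "hidden layer")
})

test_that("linear maps compute the affine map exactly", {
  sp <- transform_spec("linear")
  m <- braid:::new_map(3L, 2L, sp)
  m$layers[[1]]$W <- matrix(1:6, 3, 2)
  m$layers[[1]]$b <- c(0.5, -1)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(braid:::map_apply(m, X),
               X %*% matrix(1:6, 3, 2) +
                 matrix(c(0.5, -1), 4, 2, byrow = TRUE))
})

test_that("reverse-mode map gradients match finite differences", {
  set.seed(3)
  for (act in c("relu", "tanh")) {
    sp <- transform_spec("nonlinear", hidden_units = 7L, activation = act)
    m <- braid:::with_seed(4, braid:::new_map(3L, 2L, sp))
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(20), 10, 2)
    fw <- braid:::map_forward(m, X, need_cache = TRUE)
    dOut <- 2 * (fw$out - Y) / length(Y)
    bk <- braid:::map_backward(m, fw, dOut)
    loss <- function(mm) mean((braid:::map_apply(mm, X) - Y)^2)
    eps <- 1e-6
    for (l in 1:2) {
      i <- sample(length(m$layers[[l]]$W), 1)
      mp <- m; mp$layers[[l]]$W[i] <- mp$layers[[l]]$W[i] + eps
      mm <- m; mm$layers[[l]]$W[i] <- mm$layers[[l]]$W[i] - eps
      expect_equal(bk$grads[[l]]$W[i], (loss(mp) - loss(mm)) / (2 * eps),
                   tolerance = 1e-5)
    }
    # gradient wrt inputs
    j <- 5L
    Xp <- X; Xp[j] <- Xp[j] + eps
    Xm <- X; Xm[j] <- Xm[j] - eps
    num <- (mean((braid:::map_apply(m, Xp) - Y)^2) -
              mean((braid:::map_apply(m, Xm) - Y)^2)) / (2 * eps)
    expect_equal(bk$dX[j], num, tolerance = 1e-5)
  }
})

test_that("origin Jacobian matches the map's local linearization", {
  sp <- transform_spec("linear")
  m <- braid:::new_map(2L, 2L, sp)
  W <- matrix(c(0.9, 0, 0, 0.5), 2, 2)
  m$layers[[1]]$W <- W
  expect_equal(braid:::map_jacobian0(m), t(W))
  # MLP: compare to numerical Jacobian at 0
  spn <- transform_spec("nonlinear", hidden_units = 6L, activation = "tanh")
  mn <- braid:::with_seed(9, braid:::new_map(2L, 2L, spn))
  J <- braid:::map_jacobian0(mn)
  eps <- 1e-6
  for (j in 1:2) {
    e <- rep(0, 2); e[j] <- eps
    num <- (braid:::map_apply(mn, matrix(e, 1)) -
              braid:::map_apply(mn, matrix(-e, 1))) / (2 * eps)
    expect_equal(as.vector(J[, j]), as.vector(num), tolerance = 1e-5)
  }
})

test_that("affine initialization reproduces a target linear map", {
  sp <- transform_spec("nonlinear", hidden_units = 32L)
  m <- braid:::with_seed(2, braid:::new_map(3L, 2L, sp))
  W <- matrix(rnorm(6), 3, 2); b <- c(1, -2)
  m2 <- braid:::map_init_affine(m, W, b, seed = 5)
  X <- matrix(rnorm(600), 200, 3)
  tgt <- X %*% W + matrix(b, 200, 2, byrow = TRUE)
  rel <- sqrt(mean((braid:::map_apply(m2, X) - tgt)^2)) / sd(tgt)
  expect_lt(rel, 0.05)
})
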