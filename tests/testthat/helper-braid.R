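# Shared fixtures: everything is generated in code at test time.

# a small, fast configuration for unit tests (not the study conditions)
quick_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 40L, static_epochs = 60L, patience = 15L,
         hidden_units = 16L, seg_len = 64L, seed = 1L), list(...))
  do.call(braid_config, args)
}

# tiny linear system + dataset for smoke-level fitting tests
tiny_sim <- function(seed = 1L, T = 1200L, n_x = 2L, ...) {
  sys <- generate_random_system(n_x = n_x, n_y = 5L, n_z = 2L, n_u = 2L,
                                nonlinearity = "none", seed = seed, ...)
  list(sys = sys, ds = simulate_system(sys, T = T, seed = seed))
}

# independent discrete Lyapunov solver (kron formula), used as an oracle
lyap_oracle <- function(A, Q) {
  n <- nrow(A)
  matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Q)), n, n)
}

# independently coded steady-state Kalman predictor (Riccati iteration plus
# a plain filter loop); deliberately separate from the package's version
kalman_oracle <- function(A, B, C, Q, R, y, u) {
  P <- Q
  for (i in 1:5000) {
    S <- C %*% P %*% t(C) + R
    K <- A %*% P %*% t(C) %*% solve(S)
    Pn <- A %*% P %*% t(A) + Q - K %*% C %*% P %*% t(A)
    if (max(abs(Pn - P)) < 1e-13) break
    P <- Pn
  }
  T <- nrow(y)
  xp <- matrix(0, T, nrow(A))
  x <- rep(0, nrow(A))
  for (k in seq_len(T - 1L)) {
    x <- as.vector(A %*% x + B %*% u[k, ] + K %*% (y[k, ] - C %*% x))
    xp[k + 1L, ] <- x
  }
  list(xp = xp, K = K)
}

# build a raw linear section with prescribed matrices (row convention)
linear_section_from <- function(WA, WK, WAfw, WKfw, WD, bD = NULL) {
  n <- ncol(WA)
  specs <- list(A = "linear", K = "linear", D = "linear", d_ft = 0L)
  sec <- braid:::new_section(n, nrow(WK), if (is.null(WKfw)) 0L else
    nrow(WKfw), ncol(WD), specs)
  sec$A$layers[[1]] <- list(W = WA, b = rep(0, n))
  sec$K$layers[[1]] <- list(W = WK, b = rep(0, n))
  sec$Afw$layers[[1]] <- list(W = WAfw, b = rep(0, n))
  if (!is.null(WKfw)) sec$Kfw$layers[[1]] <- list(W = WKfw, b = rep(0, n))
  sec$D$layers[[1]] <- list(W = WD, b = bD %||% rep(0, ncol(WD)))
  sec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
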