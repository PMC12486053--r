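# Ideal-prediction oracle for simulated systems: the steady-state Kalman
# predictor of the linear latent core (exact, since the neural map is linear
# in every simulation family), composed with the true observation maps. For
# systems with a nonlinear behavior read-out the oracle applies the true
# read-out to the Kalman-predicted latent state.

# steady-state predictor-form Kalman gain and error covariance by Riccati
# iteration
kalman_steady <- function(A, C, Q, R, tol = 1e-12, max_iter = 10000L) {
  P <- Q
  for (i in seq_len(max_iter)) {
    S <- C %*% P %*% t(C) + R
    Kg <- A %*% P %*% t(C) %*% solve(S)
    P_new <- A %*% P %*% t(A) + Q - Kg %*% C %*% P %*% t(A)
    if (max(abs(P_new - P)) < tol) return(list(K = Kg, P = P_new))
    P <- P_new
  }
  list(K = Kg, P = P)
}

#' Ideal m-step-ahead predictions from the true generating model
#'
#' Runs the steady-state Kalman predictor of the true linear latent core on
#' the dataset's neural and input series, rolls the predicted state forward
#' with the true dynamics for horizons beyond one step, and applies the true
#' observation maps. This is the accuracy ceiling against which learned
#' models are compared.
#'
#' @param model the \code{braid_sim_system} that generated \code{dataset}.
#' @param dataset the simulated \code{braid_dataset}.
#' @param horizon integer vector of prediction horizons (steps ahead).
#' @return a list with elements \code{z} and \code{y}: lists (one element per
#'   horizon) of predicted series aligned to the dataset rows, with
#'   \code{NA} in the first \code{m} rows where no prediction exists.
#' @export
ideal_prediction_oracle <- function(model, dataset, horizon = 1L) {
  if (any(horizon < 1L)) stop("horizon must be >= 1")
  y <- dataset$y; u <- dataset$u
  T <- nrow(y)
  e <- encode_input(model, u)
  A <- model$A; B <- model$B; C <- model$Cy
  R <- diag(model$v_sd^2, model$n_y)
  ks <- kalman_steady(A, C, model$Q, R)
  Kg <- ks$K
  # predictor recursion x_{k+1|k} = A x + B e(u_k) + K (y_k - C x)
  xp <- matrix(0, T, model$n_x)
  tAm <- t(A - Kg %*% C); tB <- t(B); tK <- t(Kg)
  x <- matrix(0, 1L, model$n_x)
  for (k in seq_len(T - 1L)) {
    x <- x %*% tAm + e[k, , drop = FALSE] %*% tB + y[k, , drop = FALSE] %*% tK
    xp[k + 1L, ] <- x
  }
  max_h <- max(horizon)
  G <- vector("list", max_h)
  G[[1L]] <- xp[2:T, , drop = FALSE]
  if (max_h >= 2L) {
    tA <- t(A)
    for (j in 2:max_h)
      G[[j]] <- G[[j - 1L]][seq_len(T - j), , drop = FALSE] %*% tA +
        e[j:(T - 1L), , drop = FALSE] %*% tB
  }
  bs_trace <- attr(dataset, "bs_trace")
  out_z <- vector("list", length(horizon))
  out_y <- vector("list", length(horizon))
  for (i in seq_along(horizon)) {
    m <- horizon[i]
    zi <- matrix(NA_real_, T, model$n_z)
    yi <- matrix(NA_real_, T, model$n_y)
    idx <- (m + 1L):T
    zi[idx, ] <- behavior_map_apply(model$behavior, G[[m]])
    # the behavior-specific sub-system is deterministic given the input, so
    # its ideal prediction is its true trace
    if (!is.null(bs_trace)) zi[idx, ] <- zi[idx, ] + bs_trace[idx, , drop = FALSE]
    yi[idx, ] <- G[[m]] %*% t(model$Cy)
    out_z[[i]] <- zi
    out_y[[i]] <- yi
  }
  list(z = out_z, y = out_y, horizons = horizon)
}
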