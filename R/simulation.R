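# Synthetic neural-behavioral-input systems. The ground-truth generative
# model is
#   x_{k+1} = A x_k + B e(u_k) + w_k        (linear intrinsic dynamics)
#   y_k     = Cy x_k + v_k                  (linear neural map)
#   z_k     = f_z(x_k) + eps_k              (possibly nonlinear behavior map)
# where u_k is a first-order autoregressive Gaussian input process and e()
# is the identity except for the trigonometric input-encoder variant. All
# observation maps are normalized against the exact stationary state
# covariance (discrete Lyapunov equation) so noise levels are expressed as
# per-channel signal-to-noise ratios.

#' Sinusoidal behavior read-out
#'
#' The scalar nonlinearity \code{a*sin(nu) + b*nu} applied elementwise; the
#' behavior map of the "sinusoidal Cz" simulation family.
#'
#' @param nu numeric vector (or matrix) of linear latent projections.
#' @param a amplitude of the sinusoidal term.
#' @param b slope of the linear term.
#' @return \code{a*sin(nu) + b*nu}, same shape as \code{nu}.
#' @export
apply_sinusoidal_cz <- function(nu, a, b) a * sin(nu) + b * nu

#' Generate a random ground-truth simulation system
#'
#' Draws a stable linear latent core (spectral radius sampled uniformly in
#' \code{sr_range}) driven by an autoregressive Gaussian input process, with
#' observation maps chosen by \code{nonlinearity}. Noise levels are set via
#' per-channel signal-to-noise ratios. Identical arguments and seed give a
#' bit-identical system.
#'
#' @param n_x latent state dimension.
#' @param n_y,n_z,n_u neural, behavior and input dimensions.
#' @param nonlinearity one of \code{"sinusoidal_cz"}, \code{"spiral_manifold"},
#'   \code{"trig_manifold"}, \code{"trig_input_encoder"}, \code{"none"}.
#' @param seed integer seed.
#' @param sr_range range from which the spectral radius of the true
#'   state-transition matrix is drawn.
#' @param input_pole pole of the AR(1) input process.
#' @param process_noise_frac fraction of the stationary state variance
#'   contributed by the unmeasured process noise w; the remainder is driven
#'   by the measured input.
#' @param snr_y,snr_z signal-to-noise ratios of the neural and behavior
#'   channels.
#' @param sin_a,sin_b parameters of the sinusoidal behavior read-out.
#' @param nu_sd stationary standard deviation of the latent projections
#'   entering the nonlinear behavior maps.
#' @param z_subspace_dim if set, only the leading \code{z_subspace_dim}
#'   latent coordinates drive behavior (the rest are neural-only), giving a
#'   behaviorally relevant subspace of known dimension for prioritization
#'   experiments.
#' @param behavior_specific if \code{TRUE}, attach an input-driven
#'   behavior-specific sub-system (not encoded in \code{y}) for use with
#'   \code{\link{add_behavior_specific}}.
#' @param bs_gain amplitude of the behavior-specific component, as a ratio of
#'   the encoded behavior's standard deviation.
#' @return an object of class \code{braid_sim_system}.
#' @export
generate_random_system <- function(n_x = 4L, n_y = 10L, n_z = 2L, n_u = 2L,
                                   nonlinearity = c("sinusoidal_cz",
                                                    "spiral_manifold",
                                                    "trig_manifold",
                                                    "trig_input_encoder",
                                                    "none"),
                                   seed = 1L,
                                   sr_range = c(0.5, 0.95),
                                   input_pole = 0.9,
                                   process_noise_frac = 0.01,
                                   snr_y = 4.2, snr_z = 7,
                                   sin_a = 1, sin_b = 0.122, nu_sd = 3,
                                   z_subspace_dim = NULL,
                                   behavior_specific = FALSE,
                                   bs_gain = 1) {
  nonlinearity <- match.arg(nonlinearity)
  if (min(n_x, n_y, n_z, n_u) < 1L) stop("all dimensions must be >= 1")
  if (nonlinearity == "spiral_manifold" && n_z < 2L)
    stop("spiral manifold requires n_z >= 2")
  with_seed(derive_seed(seed, "system"), {
    rho <- stats::runif(1, sr_range[1], sr_range[2])
    A_raw <- matrix(stats::rnorm(n_x * n_x), n_x, n_x)
    A <- A_raw * (rho / spectral_radius(A_raw))
    Q <- diag(0.01, n_x)
    B_raw <- matrix(stats::rnorm(n_x * n_u), n_x, n_u)
    # AR(1) input, unit stationary variance per channel
    input <- list(pole = input_pole, innov_sd = sqrt(1 - input_pole^2))
    enc <- NULL
    if (nonlinearity == "trig_input_encoder") {
      enc <- list(P = matrix(stats::rnorm(n_u * n_u, sd = 1), n_u, n_u),
                  q = stats::runif(n_u, -pi / 2, pi / 2))
    }
    if (behavior_specific) {
      if (n_u < 2L)
        stop("behavior_specific requires n_u >= 2 (one input channel is ",
             "reserved for the non-encoded pathway)")
      # the last input channel bypasses the recorded region entirely, so the
      # behavior-specific dynamics it drives are not encoded in y
      B_raw[, n_u] <- 0
    }
    # set the split of stationary state variance between the unmeasured
    # process noise (fraction process_noise_frac) and the measured input
    P_w_raw <- dlyap(A, Q)
    P_u_raw <- input_driven_cov(A, B_raw, input, enc, seed)
    c_w <- process_noise_frac / mean(diag(P_w_raw))
    c_u <- (1 - process_noise_frac) / mean(diag(P_u_raw))
    Q <- Q * c_w
    B <- B_raw * sqrt(c_u)
    P_x <- P_w_raw * c_w + input_driven_cov(A, B, input, enc, seed)
    # neural map: unit signal variance per channel; when a behaviorally
    # relevant subspace is declared, its dims carry a minority of the
    # neural variance (most neural variance is behavior-irrelevant)
    Cy <- matrix(stats::rnorm(n_y * n_x), n_y, n_x)
    if (!is.null(z_subspace_dim) && z_subspace_dim < n_x)
      Cy[, seq_len(z_subspace_dim)] <- 0.35 * Cy[, seq_len(z_subspace_dim)]
    Cy <- Cy / sqrt(rowSums((Cy %*% P_x) * Cy))
    v_sd <- rep(1 / sqrt(snr_y), n_y)
    bmap <- make_behavior_map(nonlinearity, n_x, n_z, P_x,
                              sin_a, sin_b, nu_sd, seed,
                              z_subspace_dim)
    eps_sd <- sqrt(bmap$signal_var / snr_z)
    bs <- NULL
    if (behavior_specific) {
      ang <- stats::runif(1, 0.15, 0.5)
      A3 <- 0.85 * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      K3_raw <- matrix(0, 2, n_u)
      K3_raw[, n_u] <- stats::rnorm(2)
      P3 <- input_driven_cov(A3, K3_raw, input, enc, seed)
      C3_raw <- matrix(stats::rnorm(n_z * 2), n_z, 2)
      comp_var <- rowSums((C3_raw %*% P3) * C3_raw)
      C3 <- C3_raw * bs_gain * sqrt(bmap$signal_var / comp_var)
      bs <- list(A3 = A3, K3 = K3_raw, C3 = C3, gain = bs_gain)
    }
    structure(list(n_x = n_x, n_y = n_y, n_z = n_z, n_u = n_u,
                   nonlinearity = nonlinearity,
                   A = A, B = B, Cy = Cy, Q = Q,
                   v_sd = v_sd, eps_sd = eps_sd,
                   behavior = bmap, input = input, input_encoder = enc,
                   behavior_specific = bs,
                   P_x = P_x, seed = seed),
              class = "braid_sim_system")
  })
}

#' @export
print.braid_sim_system <- function(x, ...) {
  cat(sprintf(
    "braid_sim_system: n_x=%d n_y=%d n_z=%d n_u=%d, %s map, |eig(A)|max=%.3f\n",
    x$n_x, x$n_y, x$n_z, x$n_u, x$nonlinearity, spectral_radius(x$A)))
  invisible(x)
}

#' True intrinsic-dynamics eigenvalues of a simulation system
#' @param model a \code{braid_sim_system}.
#' @return complex eigenvalues of the true state-transition matrix, sorted by
#'   modulus (descending) then argument.
#' @export
true_eigenvalues <- function(model) {
  sort_eigs(eigen(model$A, only.values = TRUE)$values)
}

sort_eigs <- function(ev) ev[order(-Mod(ev), Arg(ev))]

# encoded input as it enters the state update
encode_input <- function(model, u) {
  if (is.null(model$input_encoder)) return(u)
  sin(sweep_add_row(u %*% t(model$input_encoder$P), model$input_encoder$q))
}

# stationary covariance of the input-driven state component; exact Lyapunov
# solution for linear encoding, seeded moment simulation for the
# trigonometric input encoder (whose transformed-input autocovariance has no
# convenient closed form)
input_driven_cov <- function(A, B, input, enc, seed) {
  n_x <- nrow(A); n_u <- ncol(B)
  if (is.null(enc)) {
    M <- rbind(cbind(A, B), cbind(matrix(0, n_u, n_x),
                                  diag(input$pole, n_u)))
    Qa <- diag(c(rep(0, n_x), rep(input$innov_sd^2, n_u)), n_x + n_u)
    return(dlyap(M, Qa)[seq_len(n_x), seq_len(n_x), drop = FALSE])
  }
  with_seed(derive_seed(seed, "moments"), {
    Tc <- 20000L
    u <- sim_ar1(Tc, n_u, input)
    e <- sin(sweep_add_row(u %*% t(enc$P), enc$q))
    e <- sweep(e, 2L, colMeans(e))
    x <- matrix(0, Tc, n_x)
    tA <- t(A); tB <- t(B)
    for (k in seq_len(Tc - 1L))
      x[k + 1L, ] <- x[k, , drop = FALSE] %*% tA + e[k, , drop = FALSE] %*% tB
    stats::cov(x[-seq_len(200L), , drop = FALSE])
  })
}

sim_ar1 <- function(T, n_u, input) {
  eta <- matrix(stats::rnorm(T * n_u, sd = input$innov_sd), T, n_u)
  apply(eta, 2L, function(e)
    as.numeric(stats::filter(e, input$pole, method = "recursive")))
}

# Build the deterministic behavior map and its per-channel signal variance.
make_behavior_map <- function(nonlinearity, n_x, n_z, P_x,
                              sin_a, sin_b, nu_sd, seed,
                              z_subspace_dim = NULL) {
  mask <- rep(1, n_x)
  if (!is.null(z_subspace_dim)) {
    if (z_subspace_dim < 1L || z_subspace_dim > n_x)
      stop("z_subspace_dim must be in [1, n_x]")
    mask[seq_len(n_x) > z_subspace_dim] <- 0
  }
  unit_rows <- function(C, sd_target) {
    C <- C * matrix(mask, nrow(C), n_x, byrow = TRUE)
    C * sd_target / sqrt(rowSums((C %*% P_x) * C))
  }
  bmap <- switch(nonlinearity,
    none = ,
    trig_input_encoder = {
      C <- unit_rows(matrix(stats::rnorm(n_z * n_x), n_z, n_x), 1)
      list(type = "linear", C = C)
    },
    sinusoidal_cz = {
      C <- unit_rows(matrix(stats::rnorm(n_z * n_x), n_z, n_x), nu_sd)
      list(type = "sinusoidal", C = C, a = sin_a, b = sin_b)
    },
    spiral_manifold = {
      Cr <- unit_rows(matrix(stats::rnorm(n_x), 1, n_x), 0.4)
      Ct <- unit_rows(matrix(stats::rnorm(n_x), 1, n_x), 2.2)
      E <- if (n_z == 2L) diag(2) else qr.Q(qr(matrix(stats::rnorm(n_z * 2),
                                                      n_z, 2)))
      list(type = "spiral", Cr = Cr, Ct = Ct, r0 = 1, E = E)
    },
    trig_manifold = {
      C1 <- unit_rows(matrix(stats::rnorm(n_z * n_x), n_z, n_x), 2)
      C2 <- unit_rows(matrix(stats::rnorm(n_z * n_x), n_z, n_x), 2)
      p <- stats::rnorm(n_z); q <- stats::rnorm(n_z)
      list(type = "trig", C1 = C1, C2 = C2, p = p, q = q)
    })
  # per-channel deterministic signal variance by Gaussian Monte Carlo on the
  # exact stationary latent covariance (seeded, so reproducible)
  Z <- with_seed(derive_seed(seed, "bvar"), {
    n_mc <- 20000L
    L <- chol_psd(P_x)
    X <- matrix(stats::rnorm(n_mc * n_x), n_mc, n_x) %*% L
    behavior_map_apply(bmap, X)
  })
  bmap$signal_var <- apply(Z, 2L, stats::var)
  bmap
}

chol_psd <- function(P) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(P)) %*% t(e$vectors))
}

# deterministic part of z given latent states (rows of X)
behavior_map_apply <- function(bmap, X) {
  switch(bmap$type,
    linear = X %*% t(bmap$C),
    sinusoidal = apply_sinusoidal_cz(X %*% t(bmap$C), bmap$a, bmap$b),
    spiral = {
      r <- bmap$r0 + as.vector(X %*% t(bmap$Cr))
      th <- as.vector(X %*% t(bmap$Ct))
      cbind(r * cos(th), r * sin(th)) %*% t(bmap$E)
    },
    trig = {
      sweep_mult <- function(M, s) M * matrix(s, nrow(M), length(s),
                                              byrow = TRUE)
      sweep_mult(sin(X %*% t(bmap$C1)), bmap$p) +
        sweep_mult(cos(X %*% t(bmap$C2)), bmap$q)
    })
}

#' Simulate a dataset from a ground-truth system
#'
#' Rolls the generative recursion forward with sampled process, observation
#' and input noise, discards a burn-in prefix of
#' \code{max(100, 10*n_x)} samples so the returned series is approximately
#' stationary, and packages the result as a \code{\link{braid_dataset}}.
#'
#' @param model a \code{braid_sim_system}.
#' @param T number of samples to return (after burn-in).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param n_folds contiguous cross-validation folds to assign.
#' @return a \code{braid_dataset}; the true latent trajectory is attached as
#'   attribute \code{"x_true"} for oracle-based tests.
#' @export
simulate_system <- function(model, T, seed = 1L, n_folds = 2L) {
  if (T < 2L * model$n_x) stop("T must be at least 2*n_x")
  burn <- max(100L, 10L * model$n_x)
  T_tot <- T + burn
  with_seed(derive_seed(seed, "simulate"), {
    u <- sim_ar1(T_tot, model$n_u, model$input)
    e <- encode_input(model, u)
    w <- matrix(stats::rnorm(T_tot * model$n_x), T_tot, model$n_x) %*%
      chol_psd(model$Q)
    v <- matrix(stats::rnorm(T_tot * model$n_y), T_tot, model$n_y) %*%
      diag(model$v_sd, model$n_y)
    eps <- matrix(stats::rnorm(T_tot * model$n_z), T_tot, model$n_z) %*%
      diag(model$eps_sd, model$n_z)
    x <- matrix(0, T_tot, model$n_x)
    tA <- t(model$A); tB <- t(model$B)
    for (k in seq_len(T_tot - 1L)) {
      x[k + 1L, ] <- x[k, , drop = FALSE] %*% tA +
        e[k, , drop = FALSE] %*% tB + w[k, , drop = FALSE]
      if (!all(is.finite(x[k + 1L, ])) || max(abs(x[k + 1L, ])) > 1e8)
        stop("state rollout diverged at time step ", k + 1L)
    }
    keep <- (burn + 1L):T_tot
    y <- x %*% t(model$Cy) + v
    z <- behavior_map_apply(model$behavior, x) + eps
    ds <- braid_dataset(y[keep, , drop = FALSE], z[keep, , drop = FALSE],
                        u[keep, , drop = FALSE], dt = 1,
                        n_folds = n_folds, seed = seed)
    attr(ds, "x_true") <- x[keep, , drop = FALSE]
    ds
  })
}

#' Add an input-driven behavior-specific component to a simulated dataset
#'
#' Augments the behavior series with the output of a separate latent
#' sub-system that is driven by the measured input but never enters the map
#' producing the neural activity; such dynamics are predictable from the
#' input history yet not encoded in \code{y}. The added component's
#' ground-truth trace is attached as attribute \code{"bs_trace"}.
#'
#' @param dataset a \code{braid_dataset} simulated from \code{model}.
#' @param model a \code{braid_sim_system} created with
#'   \code{behavior_specific = TRUE}.
#' @param seed unused when the sub-system is noise-free; kept for interface
#'   stability.
#' @return the dataset with the component added to \code{z}.
#' @export
add_behavior_specific <- function(dataset, model, seed = 1L) {
  bs <- model$behavior_specific
  if (is.null(bs)) stop("model has no behavior_specific sub-system")
  if (bs$gain == 0) return(dataset)
  u <- dataset$u
  e <- encode_input(model, u)
  T <- nrow(u)
  x3 <- matrix(0, T, 2L)
  tA <- t(bs$A3); tK <- t(bs$K3)
  for (k in seq_len(T - 1L))
    x3[k + 1L, ] <- x3[k, , drop = FALSE] %*% tA + e[k, , drop = FALSE] %*% tK
  trace <- x3 %*% t(bs$C3)
  dataset$z <- dataset$z + trace
  attr(dataset, "bs_trace") <- trace
  attr(dataset, "x3_true") <- x3
  dataset
}
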