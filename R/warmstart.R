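# Closed-form linear initialization of a section before gradient training.
# A ridge regression from windows of past section inputs to stacked future
# targets is rank-reduced (SVD) to the section's state dimension, giving an
# initial state sequence; the predictor-form maps are then obtained by
# regression, and the generative-form recursion by substituting the
# predictable (neural) part of the observations with its state read-out:
#   x_{k+1} = x A + y Ky + u Ku,  y ~ x Cyh  =>  Afw = A + Cyh Ky, Kfw = Ku.
# Nonlinear maps are initialized to mimic the linear solution through their
# random hidden features, so gradient training starts at the linear
# optimum and only has to learn the nonlinear structure.

ridge_solve <- function(X, Y, lam_rel = 1e-6) {
  Xa <- cbind(X, 1)
  XtX <- crossprod(Xa)
  lam <- lam_rel * mean(diag(XtX))
  solve(XtX + diag(lam, ncol(Xa)), crossprod(Xa, Y))
}

lag_matrix <- function(M, p, rows) {
  do.call(cbind, lapply(seq_len(p), function(l)
    M[rows - l, , drop = FALSE]))
}

# regularized canonical correlation directions between past windows and
# futures; returns the past-side projection (dP x k)
reg_cca_dirs <- function(P, F, k, lam_rel = 1e-8) {
  whiten <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% diag(1 / sqrt(ev), length(ev)) %*% t(e$vectors)
  }
  Sxx <- crossprod(P) / nrow(P)
  Syy <- crossprod(F) / nrow(F)
  Sxx <- Sxx + diag(lam_rel * mean(diag(Sxx)), ncol(P))
  Syy <- Syy + diag(lam_rel * mean(diag(Syy)), ncol(F))
  Wx <- whiten(Sxx)
  Wy <- whiten(Syy)
  Kmat <- Wx %*% (crossprod(P, F) / nrow(P)) %*% Wy
  sv <- svd(Kmat, nu = min(k, min(dim(Kmat))), nv = 0L)
  Wx %*% sv$u
}

linear_section_init <- function(obs, u_roll, tgt, n, fut_len, ny_obs,
                                p = 12L) {
  T <- nrow(obs)
  fut_len <- min(fut_len, max(2L, (T - p) %/% 4L))
  rows <- (p + 1L):(T - fut_len)
  Fz <- do.call(cbind, lapply(0:(fut_len - 1L), function(j)
    tgt[rows + j, , drop = FALSE]))
  F <- Fz
  if (ny_obs > 0L) {
    # neural futures sharpen the basis: the target map may be nonlinear in
    # the state while the neural map is linear in it
    Fy <- do.call(cbind, lapply(0:(fut_len - 1L), function(j)
      obs[rows + j, seq_len(ny_obs), drop = FALSE]))
    F <- cbind(Fz, Fy)
  }
  P <- lag_matrix(obs, p, rows)
  Pc <- sweep(P, 2L, colMeans(P))
  Fc <- sweep(F, 2L, colMeans(F))
  # canonical-variate state basis between past windows and futures; the
  # stage's own training loss (behavior-only in stage 1) is what enforces
  # prioritization, so the initialization basis can stay neutral
  dirs <- reg_cca_dirs(Pc, Fc, min(n, ncol(Pc), ncol(Fc)))
  X <- Pc %*% dirs
  # rescale to unit variance per coordinate for well-conditioned training
  X <- sweep(X, 2L, pmax(apply(X, 2L, stats::sd), 1e-8), "/")
  if (ncol(X) < n) X <- cbind(X, matrix(0, nrow(X), n - ncol(X)))
  N <- nrow(X)
  # predictor-form recursion and read-out by regression
  WA_full <- ridge_solve(cbind(X[-N, , drop = FALSE],
                               obs[rows[-N], , drop = FALSE]),
                         X[-1L, , drop = FALSE])
  WA <- WA_full[seq_len(n), , drop = FALSE]
  WK <- WA_full[(n + 1L):(n + ncol(obs)), , drop = FALSE]
  WD_full <- ridge_solve(X, tgt[rows, , drop = FALSE])
  Wc <- if (ny_obs > 0L)
    ridge_solve(X, obs[rows, seq_len(ny_obs), drop = FALSE])[
      seq_len(n), , drop = FALSE] else NULL
  WAfw <- WA
  if (ny_obs > 0L)
    WAfw <- WA + Wc %*% WK[seq_len(ny_obs), , drop = FALSE]
  # clip to a stable spectral radius so early rollouts cannot diverge
  sr <- spectral_radius(t(WAfw))
  if (sr > 0.99) WAfw <- WAfw * (0.99 / sr)
  n_u <- if (is.null(u_roll)) 0L else ncol(u_roll)
  WKfw <- if (n_u > 0L && ny_obs + n_u <= ncol(obs))
    WK[(ny_obs + 1L):(ny_obs + n_u), , drop = FALSE] else NULL
  list(A = list(W = WA, b = rep(0, n)),
       X = X, rows = rows,
       K = list(W = WK, b = rep(0, n)),
       Afw = list(W = WAfw, b = rep(0, n)),
       Kfw = if (!is.null(WKfw)) list(W = WKfw, b = rep(0, n)),
       D = list(W = WD_full[seq_len(n), , drop = FALSE],
                b = as.vector(WD_full[n + 1L, ])))
}

# set a map's weights to (an approximation of) the affine map W, b; exact
# for linear maps, least-squares through the random hidden features for MLPs
map_init_affine <- function(map, W, b, seed = 1L) {
  if (is.null(map) || is.null(W)) return(map)
  nl <- length(map$layers)
  if (nl == 1L) {
    map$layers[[1L]]$W <- W
    map$layers[[1L]]$b <- b
    return(map)
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(2000L * map$d_in, sd = 1.5), ncol = map$d_in)
    tgt <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
    a <- X
    for (l in seq_len(nl - 1L)) {
      Ly <- map$layers[[l]]
      a <- act_fun(sweep_add_row(a %*% Ly$W, Ly$b), map$activation)
    }
    Wout <- ridge_solve(a, tgt)
    map$layers[[nl]]$W <- Wout[seq_len(ncol(a)), , drop = FALSE]
    map$layers[[nl]]$b <- as.vector(Wout[ncol(a) + 1L, ])
  })
  map
}

# warm-start all six maps of a section from the linear solution
warm_start_section <- function(sec, obs, u_roll, tgt, horizons, ny_obs,
                               seed = 1L, feedthrough = NULL) {
  ini <- linear_section_init(obs, u_roll, tgt, sec$state_dim,
                             fut_len = max(horizons) + 3L, ny_obs = ny_obs)
  sec$A <- map_init_affine(sec$A, ini$A$W, ini$A$b, derive_seed(seed, "wA"))
  sec$K <- map_init_affine(sec$K, ini$K$W, ini$K$b, derive_seed(seed, "wK"))
  if (max(horizons) > 1L) {
    # the generative-form maps enter the computation graph only through
    # multi-step horizons; with a 1-step-only loss they are neither
    # initialized from data nor updated, so such a model has no basis to
    # claim learned intrinsic dynamics
    sec$Afw <- map_init_affine(sec$Afw, ini$Afw$W, ini$Afw$b,
                               derive_seed(seed, "wAfw"))
    if (!is.null(sec$Kfw) && !is.null(ini$Kfw))
      sec$Kfw <- map_init_affine(sec$Kfw, ini$Kfw$W, ini$Kfw$b,
                                 derive_seed(seed, "wKfw"))
  }
  if (sec$d_ft == 0L) {
    sec$D <- map_init_affine(sec$D, ini$D$W, ini$D$b,
                             derive_seed(seed, "wD"))
  } else if (!is.null(feedthrough)) {
    Wd <- ridge_solve(cbind(ini$X, feedthrough[ini$rows, , drop = FALSE]),
                      tgt[ini$rows, , drop = FALSE])
    d_in <- sec$state_dim + sec$d_ft
    sec$D <- map_init_affine(sec$D, Wd[seq_len(d_in), , drop = FALSE],
                             as.vector(Wd[d_in + 1L, ]),
                             derive_seed(seed, "wD"))
  }
  sec
}

# After warm start, pre-fit a nonlinear read-out statically on the initial
# state chain (frozen states), so joint training starts with both the state
# space and the read-out shape roughly right.
prefit_decoder <- function(sec, obs, u_roll, targets, horizons,
                           control, seed) {
  if (sec$D$mode != "nonlinear" || sec$d_ft != 0L) return(sec)
  XP <- section_filter(sec, obs)
  G <- section_mstep_chain(sec, XP, u_roll, max(horizons))
  T <- nrow(obs)
  X <- do.call(rbind, lapply(horizons, function(m) G[[m]]))
  Y <- do.call(rbind, lapply(seq_along(horizons), function(i) {
    tg <- if (is.list(targets)) targets[[i]] else targets
    tg[(horizons[i] + 1L):T, , drop = FALSE]
  }))
  spec <- transform_spec("nonlinear",
                         hidden_layers = length(sec$D$layers) - 1L,
                         hidden_units = nrow(sec$D$layers[[
                           length(sec$D$layers)]]$W),
                         activation = sec$D$activation)
  sec$D <- fit_static_map(X, Y, spec, control = control, seed = seed,
                          init_map = sec$D)
  sec
}
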