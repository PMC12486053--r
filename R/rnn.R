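# Core recurrent machinery: one model "section" couples a predictor-form
# RNN, x_{k+1|k} = A(x_{k|k-1}) + K(o_k), with a generative-form RNN,
# x_{k+m|k} = Afw(x_{k+m-1|k}) + Kfw(u_{k+m-1}), and a read-out map D.
# Training minimizes the summed m-step-ahead MSE across the configured
# horizons by full-batch adaptive gradient descent with exact reverse-mode
# gradients (backpropagation through time over truncated segments).

new_section <- function(state_dim, d_obs, d_u, d_out, specs,
                        hidden_units = 64L, activation = "relu") {
  spec_of <- function(mode) {
    transform_spec(mode, hidden_layers = 1L, hidden_units = hidden_units,
                   activation = activation)
  }
  structure(list(
    state_dim = as.integer(state_dim), d_obs = d_obs, d_u = d_u,
    A   = new_map(state_dim, state_dim, spec_of(specs$A), init_identity = TRUE),
    K   = new_map(d_obs, state_dim, spec_of(specs$K), init_scale = 0.5),
    Afw = new_map(state_dim, state_dim, spec_of(specs$A), init_identity = TRUE),
    Kfw = if (d_u > 0L) new_map(d_u, state_dim, spec_of(specs$K),
                                init_scale = 0.5) else NULL,
    D   = new_map(state_dim + (specs$d_ft %||% 0L), d_out,
                  spec_of(specs$D), init_scale = 0.5),
    d_ft = specs$d_ft %||% 0L,
    specs = specs
  ), class = "braid_section")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

train_control <- function(epochs = 500L, lr = 1e-3, seg_len = 128L,
                          batch_segments = 16L, val_frac = 0.15,
                          patience = 40L, verbose = FALSE) {
  list(epochs = as.integer(epochs), lr = lr, seg_len = as.integer(seg_len),
       batch_segments = as.integer(batch_segments), val_frac = val_frac,
       patience = as.integer(patience), verbose = isTRUE(verbose))
}

# contiguous segment start indices; a final overlapping segment covers the tail
segment_starts <- function(T, L) {
  if (T < L) stop("series shorter than one segment")
  starts <- seq.int(1L, T - L + 1L, by = L)
  if (starts[length(starts)] + L - 1L < T) starts <- c(starts, T - L + 1L)
  starts
}

# rows of `mat` at segment-relative times `t_range`, pooled t-major
# (block of length(starts) rows per t)
pool_rows <- function(mat, starts, t_range) {
  idx <- as.vector(vapply(as.integer(t_range),
                          function(t) as.integer(starts) + t - 1L,
                          integer(length(starts))))
  mat[idx, , drop = FALSE]
}

# Precompute pooled segment views of a series for training.
make_seg_data <- function(obs, u_roll, targets, feedthrough,
                          starts, L, horizons) {
  S <- length(starts)
  max_h <- max(horizons)
  o_list <- lapply(seq_len(L - 1L), function(k)
    obs[starts + k - 1L, , drop = FALSE])
  u_pool <- vector("list", max_h)
  if (max_h >= 2L && !is.null(u_roll) && ncol(u_roll) > 0L) {
    for (j in 2:max_h) u_pool[[j]] <- pool_rows(u_roll, starts, j:(L - 1L))
  }
  tgt_pool <- vector("list", length(horizons))
  ft_pool <- vector("list", length(horizons))
  for (i in seq_along(horizons)) {
    m <- horizons[i]
    tg <- if (is.list(targets)) targets[[i]] else targets
    tgt_pool[[i]] <- pool_rows(tg, starts, (m + 1L):L)
    if (!is.null(feedthrough))
      ft_pool[[i]] <- pool_rows(feedthrough, starts, (m + 1L):L)
  }
  list(S = S, L = L, o_list = o_list, u_pool = u_pool,
       tgt_pool = tgt_pool, ft_pool = ft_pool,
       has_ft = !is.null(feedthrough))
}

# Forward pass over pooled segments; optionally caches for backprop.
section_forward_seg <- function(sec, sd, horizons, hweights,
                                need_cache = FALSE) {
  S <- sd$S; L <- sd$L
  n <- sec$state_dim
  max_h <- max(horizons)
  XP <- vector("list", L)
  XP[[1L]] <- matrix(0, S, n)
  cA <- if (need_cache) vector("list", L - 1L) else NULL
  cK <- if (need_cache) vector("list", L - 1L) else NULL
  for (k in seq_len(L - 1L)) {
    fa <- map_forward(sec$A, XP[[k]], need_cache)
    fk <- map_forward(sec$K, sd$o_list[[k]], need_cache)
    XP[[k + 1L]] <- fa$out + fk$out
    if (need_cache) { cA[[k]] <- fa; cK[[k]] <- fk }
  }
  G <- vector("list", max_h)
  cAfw <- if (need_cache) vector("list", max_h) else NULL
  cKfw <- if (need_cache) vector("list", max_h) else NULL
  G[[1L]] <- do.call(rbind, XP[2:L])
  if (max_h >= 2L) {
    for (j in 2:max_h) {
      keep <- (L - j) * S
      Gin <- G[[j - 1L]][seq_len(keep), , drop = FALSE]
      fa <- map_forward(sec$Afw, Gin, need_cache)
      out <- fa$out
      fk <- NULL
      if (!is.null(sec$Kfw)) {
        fk <- map_forward(sec$Kfw, sd$u_pool[[j]], need_cache)
        out <- out + fk$out
      }
      G[[j]] <- out
      if (need_cache) { cAfw[[j]] <- fa; cKfw[[j]] <- fk }
    }
  }
  preds <- vector("list", length(horizons))
  cD <- if (need_cache) vector("list", length(horizons)) else NULL
  loss <- 0
  for (i in seq_along(horizons)) {
    m <- horizons[i]
    Din <- G[[m]]
    if (sd$has_ft) Din <- cbind(Din, sd$ft_pool[[i]])
    fd <- map_forward(sec$D, Din, need_cache)
    preds[[i]] <- fd$out
    if (need_cache) cD[[i]] <- fd
    loss <- loss + hweights[i] * mean((fd$out - sd$tgt_pool[[i]])^2)
  }
  list(loss = loss, XP = XP, G = G, preds = preds,
       cA = cA, cK = cK, cAfw = cAfw, cKfw = cKfw, cD = cD)
}

acc_grads <- function(a, b) if (is.null(a)) b else tree_map2(`+`, a, b)

# Full reverse-mode pass matching section_forward_seg.
section_backward_seg <- function(sec, sd, fw, horizons, hweights) {
  S <- sd$S; L <- sd$L
  max_h <- max(horizons)
  gA <- NULL; gK <- NULL; gAfw <- NULL; gKfw <- NULL; gD <- NULL
  dG <- vector("list", max_h)
  for (i in seq_along(horizons)) {
    m <- horizons[i]
    P <- fw$preds[[i]]
    dP <- 2 * hweights[i] * (P - sd$tgt_pool[[i]]) / length(P)
    bk <- map_backward(sec$D, fw$cD[[i]], dP)
    gD <- acc_grads(gD, bk$grads)
    dstate <- bk$dX[, seq_len(sec$state_dim), drop = FALSE]
    dG[[m]] <- if (is.null(dG[[m]])) dstate else dG[[m]] + dstate
  }
  if (max_h >= 2L) {
    for (j in max_h:2L) {
      if (is.null(dG[[j]])) next
      bk <- map_backward(sec$Afw, fw$cAfw[[j]], dG[[j]])
      gAfw <- acc_grads(gAfw, bk$grads)
      keep <- (L - j) * S
      if (is.null(dG[[j - 1L]]))
        dG[[j - 1L]] <- matrix(0, (L - j + 1L) * S, sec$state_dim)
      dG[[j - 1L]][seq_len(keep), ] <-
        dG[[j - 1L]][seq_len(keep), , drop = FALSE] + bk$dX
      if (!is.null(sec$Kfw)) {
        bku <- map_backward(sec$Kfw, fw$cKfw[[j]], dG[[j]], need_dx = FALSE)
        gKfw <- acc_grads(gKfw, bku$grads)
      }
    }
  }
  # unstack dG[[1]] (blocks k = 1..L-1 correspond to XP[[k+1]])
  dXP <- vector("list", L)
  if (!is.null(dG[[1L]])) {
    for (k in seq_len(L - 1L))
      dXP[[k + 1L]] <- dG[[1L]][((k - 1L) * S + 1L):(k * S), , drop = FALSE]
  }
  for (k in L:2L) {
    delta <- dXP[[k]]
    if (is.null(delta)) next
    bk <- map_backward(sec$A, fw$cA[[k - 1L]], delta)
    gA <- acc_grads(gA, bk$grads)
    dXP[[k - 1L]] <- if (is.null(dXP[[k - 1L]])) bk$dX else
      dXP[[k - 1L]] + bk$dX
    bkk <- map_backward(sec$K, fw$cK[[k - 1L]], delta, need_dx = FALSE)
    gK <- acc_grads(gK, bkk$grads)
  }
  list(A = gA, K = gK, Afw = gAfw, Kfw = gKfw, D = gD)
}

section_get_params <- function(sec, trained) {
  p <- list()
  for (nm in trained) if (!is.null(sec[[nm]])) p[[nm]] <- sec[[nm]]$layers
  p
}

section_set_params <- function(sec, params) {
  for (nm in names(params)) sec[[nm]]$layers <- params[[nm]]
  sec
}

#' @keywords internal
train_section <- function(sec, obs, u_roll, targets, horizons,
                          hweights = rep(1, length(horizons)),
                          feedthrough = NULL,
                          control = train_control(), seed = 1L) {
  T <- nrow(obs)
  max_h <- max(horizons)
  L <- min(control$seg_len, T)
  if (L <= max_h + 1L)
    stop("segment length must exceed the longest horizon + 1")
  starts <- segment_starts(T, L)
  S <- length(starts)
  n_val <- if (S >= 4L) max(1L, round(control$val_frac * S)) else 0L
  tr_starts <- if (n_val > 0L) starts[seq_len(S - n_val)] else starts
  va_starts <- if (n_val > 0L) starts[(S - n_val + 1L):S] else NULL
  # fixed minibatches of whole segments (seeded order), one Adam update per
  # batch; early stopping monitors the held-out segment slice
  sd_va <- if (!is.null(va_starts))
    make_seg_data(obs, u_roll, targets, feedthrough, va_starts, L, horizons)
  batches <- with_seed(derive_seed(seed, "batches"), {
    ord <- sample(length(tr_starts))
    split(tr_starts[ord],
          ceiling(seq_along(ord) / control$batch_segments))
  })
  sd_batches <- lapply(batches, function(st)
    make_seg_data(obs, u_roll, targets, feedthrough, sort(st), L, horizons))
  trained <- c("A", "K", "D", if (max_h > 1L) c("Afw", "Kfw"))
  params <- section_get_params(sec, trained)
  opt <- adam_init(params)
  best_loss <- Inf
  best_params <- params
  since_best <- 0L
  hist_tr <- numeric(control$epochs)
  hist_va <- numeric(control$epochs)
  n_ep <- 0L
  with_seed(seed, {
    for (ep in seq_len(control$epochs)) {
      ep_loss <- 0
      for (sd_b in sd_batches) {
        fw <- section_forward_seg(sec, sd_b, horizons, hweights,
                                  need_cache = TRUE)
        if (!is.finite(fw$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        gr <- section_backward_seg(sec, sd_b, fw, horizons, hweights)
        gr <- gr[trained]
        gr <- gr[!vapply(gr, is.null, logical(1))]
        st <- adam_step(opt, params[names(gr)], gr, lr = control$lr)
        opt <- st$state
        params[names(gr)] <- st$params
        sec <- section_set_params(sec, params)
        ep_loss <- ep_loss + fw$loss
      }
      ep_loss <- ep_loss / length(sd_batches)
      mon <- if (!is.null(sd_va))
        section_forward_seg(sec, sd_va, horizons, hweights)$loss
      else ep_loss
      n_ep <- ep
      hist_tr[ep] <- ep_loss
      hist_va[ep] <- mon
      if (mon < best_loss - 1e-10) {
        best_loss <- mon
        best_params <- params
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= control$patience) break
      }
      if (control$verbose && ep %% 50L == 0L)
        message(sprintf("epoch %d train %.5f val %.5f", ep, ep_loss, mon))
    }
  })
  sec <- section_set_params(sec, best_params)
  list(section = sec,
       history = data.frame(epoch = seq_len(n_ep),
                            train_loss = hist_tr[seq_len(n_ep)],
                            val_loss = hist_va[seq_len(n_ep)]),
       best_val = best_loss)
}

# ---- inference-time computations ------------------------------------------

# Causal filter over a full (unsegmented) series: returns the T x n matrix of
# 1-step-ahead predicted states x_{k|k-1}, with x_{1|0} = 0.
section_filter <- function(sec, obs) {
  T <- nrow(obs)
  n <- sec$state_dim
  XP <- matrix(0, T, n)
  x <- matrix(0, 1L, n)
  for (k in seq_len(T - 1L)) {
    x <- map_apply(sec$A, x) +
      map_apply(sec$K, obs[k, , drop = FALSE])
    XP[k + 1L, ] <- x
  }
  XP
}

# m-step-ahead states for all origins, via the generative-form recursion.
# Returns a list over j = 1..max_h; element j is a (T - j) x n matrix whose
# row k is x_{k+j|k}.
section_mstep_chain <- function(sec, XP, u_roll, max_h) {
  T <- nrow(XP)
  G <- vector("list", max_h)
  G[[1L]] <- XP[2:T, , drop = FALSE]
  if (max_h >= 2L) {
    for (j in 2:max_h) {
      Gin <- G[[j - 1L]][seq_len(T - j), , drop = FALSE]
      out <- map_apply(sec$Afw, Gin)
      if (!is.null(sec$Kfw))
        out <- out + map_apply(sec$Kfw,
                               u_roll[j:(T - 1L), , drop = FALSE])
      G[[j]] <- out
    }
  }
  G
}

# ---- static read-out fitting ----------------------------------------------

# Fit a map from fixed inputs to targets (states are frozen). Linear maps use
# ridge-regularized least squares in closed form; MLPs use Adam.
fit_static_map <- function(X, Y, spec, control = train_control(epochs = 400L),
                           seed = 1L, init_scale = 0.5, init_map = NULL) {
  keep <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (spec$mode == "linear") {
    Xa <- cbind(X, 1)
    XtX <- crossprod(Xa)
    lam <- 1e-8 * mean(diag(XtX))
    W <- solve(XtX + diag(lam, ncol(Xa)), crossprod(Xa, Y))
    map <- with_seed(seed, new_map(ncol(X), ncol(Y), spec))
    map$layers[[1L]]$W <- W[seq_len(ncol(X)), , drop = FALSE]
    map$layers[[1L]]$b <- as.vector(W[ncol(Xa), ])
    return(map)
  }
  n <- nrow(X)
  n_val <- max(1L, round(control$val_frac * n))
  tr <- seq_len(n - n_val)
  va <- (n - n_val + 1L):n
  map <- with_seed(seed, new_map(ncol(X), ncol(Y), spec,
                                 init_scale = init_scale))
  if (!is.null(init_map)) map$layers <- init_map$layers
  params <- list(D = map$layers)
  opt <- adam_init(params)
  best <- Inf; best_params <- params; since <- 0L
  batches <- split(tr, ceiling(seq_along(tr) / 4096L))
  with_seed(seed + 1L, {
    for (ep in seq_len(control$epochs)) {
      for (b in batches) {
        fw <- map_forward(map, X[b, , drop = FALSE], need_cache = TRUE)
        dP <- 2 * (fw$out - Y[b, , drop = FALSE]) / length(fw$out)
        bk <- map_backward(map, fw, dP, need_dx = FALSE)
        st <- adam_step(opt, params, list(D = bk$grads), lr = control$lr)
        opt <- st$state; params <- st$params
        map$layers <- params$D
      }
      mon <- mean((map_apply(map, X[va, , drop = FALSE]) -
                     Y[va, , drop = FALSE])^2)
      if (mon < best - 1e-12) { best <- mon; best_params <- params; since <- 0L }
      else { since <- since + 1L; if (since >= control$patience) break }
    }
  })
  map$layers <- best_params$D
  map
}
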