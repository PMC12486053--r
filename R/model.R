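# Model assembly and the multi-stage optimization scheme:
#   preprocessing : causal regression of behavior on neural data alone,
#                   whose output replaces behavior as the supervision target
#                   so that stage 1 only learns neurally encoded dynamics;
#   stage 1a/1b   : behaviorally relevant latent states x(1) (behavior loss),
#                   then a frozen-state neural read-out Cy(1);
#   stage 2a/2b   : neural-specific latent states x(2) on the neural residual,
#                   then a frozen-state behavior read-out Cz(2);
#   stage 3       : input-driven behavior-specific states x(3) fitted to the
#                   behavior residual from the measured input only.

#' Training and architecture configuration
#'
#' @param variant "braid" (full model), "linear_braid" (all maps forced
#'   linear), "u_braid" (unsupervised: states learned from the neural loss
#'   only, behavior decoder fitted post hoc), or "no_input_ablation"
#'   (measured inputs withheld everywhere).
#' @param horizons integer vector of prediction steps included in the
#'   training loss; horizons beyond 1 engage the generative-form maps.
#' @param hweights per-horizon loss weights (default all 1).
#' @param nonlinearity named list with entries A, K, Cy, Cz, each "linear"
#'   or "nonlinear"; the generative-form maps inherit the modes of their
#'   predictor-form counterparts.
#' @param hidden_units,activation MLP architecture for nonlinear maps.
#' @param epochs,lr,seg_len,batch_segments,val_frac,patience optimization
#'   settings: epoch cap, Adam learning rate, truncated-backpropagation
#'   segment length, segments per minibatch, and the held-out slice
#'   (fraction of training segments) plus patience used for early stopping.
#' @param static_epochs epoch cap for frozen-state read-out fitting.
#' @param preprocess logical; enable the behavior-preprocessing stage.
#' @param preprocess_dim latent dimension of the preprocessor (default: n1).
#' @param decoder_input_u logical; also feed the measured input to the
#'   read-out maps (off by default, matching states-only decoding).
#' @param seed integer seed governing all randomness of the fit.
#' @return an object of class \code{braid_config}.
#' @export
braid_config <- function(variant = c("braid", "linear_braid", "u_braid",
                                     "no_input_ablation"),
                         horizons = 1:5,
                         hweights = NULL,
                         nonlinearity = list(A = "linear", K = "linear",
                                             Cy = "linear", Cz = "linear"),
                         hidden_units = 64L, activation = "relu",
                         epochs = 250L, lr = 3e-3, seg_len = 128L,
                         batch_segments = 8L, val_frac = 0.15,
                         patience = 40L,
                         static_epochs = 200L,
                         preprocess = FALSE, preprocess_dim = NULL,
                         decoder_input_u = FALSE,
                         seed = 1L) {
  variant <- match.arg(variant)
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1L)) stop("horizons must be >= 1")
  if (is.null(hweights)) hweights <- rep(1, length(horizons))
  if (length(hweights) != length(horizons))
    stop("hweights must match horizons")
  nl <- utils::modifyList(list(A = "linear", K = "linear",
                               Cy = "linear", Cz = "linear"), nonlinearity)
  if (variant == "linear_braid")
    nl <- list(A = "linear", K = "linear", Cy = "linear", Cz = "linear")
  stopifnot(all(unlist(nl) %in% c("linear", "nonlinear")))
  structure(list(variant = variant, horizons = horizons, hweights = hweights,
                 nonlinearity = nl, hidden_units = as.integer(hidden_units),
                 activation = activation, epochs = as.integer(epochs),
                 lr = lr, seg_len = as.integer(seg_len),
                 batch_segments = as.integer(batch_segments),
                 val_frac = val_frac, patience = as.integer(patience),
                 static_epochs = as.integer(static_epochs),
                 preprocess = isTRUE(preprocess),
                 preprocess_dim = preprocess_dim,
                 decoder_input_u = isTRUE(decoder_input_u),
                 seed = as.integer(seed)),
            class = "braid_config")
}

fit_scaler <- function(M, warn_name = NULL) {
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  bad <- !is.finite(sd) | sd < 1e-12
  if (any(bad) && !is.null(warn_name))
    warning("zero-variance ", warn_name,
            " channel(s) passed through as their mean")
  sd[bad] <- 1
  list(mean = mu, sd = sd, degenerate = which(bad))
}

scale_apply <- function(M, sc) {
  if (ncol(M) == 0L) return(M)
  sweep(sweep(M, 2L, sc$mean), 2L, sc$sd, "/")
}

scale_invert <- function(M, sc) {
  if (is.null(M) || ncol(M) == 0L) return(M)
  sweep(sweep(M, 2L, sc$sd, "*"), 2L, sc$mean, "+")
}

ctrl_of <- function(config, epochs = NULL) {
  train_control(epochs = epochs %||% config$epochs, lr = config$lr,
                seg_len = config$seg_len,
                batch_segments = config$batch_segments,
                val_frac = config$val_frac, patience = config$patience)
}

# full-series m-step latent chains and additive read-out predictions for a
# fitted section; returns per-horizon T x d matrices (NA heads)
section_predict_chain <- function(fsec, obs, u_roll, horizons, readout,
                                  u_feed = NULL) {
  XP <- section_filter(fsec$sec, obs)
  G <- section_mstep_chain(fsec$sec, XP, u_roll, max(horizons))
  T <- nrow(obs)
  out <- vector("list", length(horizons))
  for (i in seq_along(horizons)) {
    m <- horizons[i]
    map <- fsec[[readout]]
    if (is.null(map)) { out[[i]] <- NULL; next }
    Din <- G[[m]]
    if (!is.null(u_feed)) Din <- cbind(Din, u_feed[(m + 1L):T, , drop = FALSE])
    P <- matrix(NA_real_, T, map$d_out)
    P[(m + 1L):T, ] <- map_apply(map, Din)
    out[[i]] <- P
  }
  attr(out, "XP") <- XP
  out
}

# pooled (state, target) pairs across horizons for frozen-state read-out fits
pool_chain_targets <- function(fsec, obs, u_roll, horizons, targets,
                               u_feed = NULL) {
  XP <- section_filter(fsec$sec, obs)
  G <- section_mstep_chain(fsec$sec, XP, u_roll, max(horizons))
  T <- nrow(obs)
  Xs <- list(); Ys <- list()
  for (i in seq_along(horizons)) {
    m <- horizons[i]
    tg <- if (is.list(targets)) targets[[i]] else targets
    Din <- G[[m]]
    if (!is.null(u_feed)) Din <- cbind(Din, u_feed[(m + 1L):T, , drop = FALSE])
    Xs[[i]] <- Din
    Ys[[i]] <- tg[(m + 1L):T, , drop = FALSE]
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys), XP = XP)
}

spec_mode <- function(config, which) {
  transform_spec(config$nonlinearity[[which]],
                 hidden_units = config$hidden_units,
                 activation = config$activation)
}

#' Fit the behavior-preprocessing regressor
#'
#' Fits a causal recurrent regressor that predicts behavior from neural data
#' alone (no measured input, and never behavior itself at inference). Its
#' output is used downstream in place of the recorded behavior as the
#' supervision target, so that the behaviorally relevant states learned in
#' stage 1 are restricted to dynamics actually encoded in the neural
#' activity.
#'
#' @param y,z training neural and behavior series (matrices, T x n).
#' @param config a \code{\link{braid_config}}; \code{preprocess_dim} sets the
#'   regressor's latent dimension.
#' @param n1 fallback latent dimension when \code{preprocess_dim} is unset.
#' @return list with \code{z_pre} (the neurally predicted behavior, T x n_z,
#'   same scale as \code{z}) and \code{regressor} (the fitted section).
#' @export
preprocess_behavior <- function(y, z, config, n1 = ncol(z)) {
  y <- as_matrix_ts(y, "y"); z <- as_matrix_ts(z, "z")
  sc_y <- fit_scaler(y); sc_z <- fit_scaler(z, warn_name = "z")
  ys <- scale_apply(y, sc_y); zs <- scale_apply(z, sc_z)
  dim_p <- config$preprocess_dim %||% n1
  specs <- list(A = config$nonlinearity$A, K = config$nonlinearity$K,
                D = config$nonlinearity$Cz, d_ft = ncol(y))
  sec <- with_seed(derive_seed(config$seed, "preproc_init"),
                   new_section(dim_p, ncol(y), 0L, ncol(z), specs,
                               config$hidden_units, config$activation))
  sec <- warm_start_section(sec, ys, NULL, zs, 1L, ncol(y),
                            derive_seed(config$seed, "preproc_ws"),
                            feedthrough = ys)
  tr <- train_section(sec, obs = ys, u_roll = NULL, targets = zs,
                      horizons = 1L, feedthrough = ys,
                      control = ctrl_of(config),
                      seed = derive_seed(config$seed, "preproc"))
  sec <- tr$section
  XP <- section_filter(sec, ys)
  z_pre_s <- map_apply(sec$D, cbind(XP, ys))
  z_pre_s[, sc_z$degenerate] <- 0  # constant channels pass through as mean
  list(z_pre = scale_invert(z_pre_s, sc_z),
       regressor = list(sec = sec, sc_y = sc_y, sc_z = sc_z),
       history = tr$history)
}

#' Fit an input-driven nonlinear latent model of neural-behavioral data
#'
#' Runs the staged optimization on a training set: optional behavior
#' preprocessing, stage 1 (behaviorally relevant states, n1 dims), stage 2
#' (neural-specific states, n2 dims), and stage 3 (input-driven
#' behavior-specific states, n3 dims). Held-out prediction afterwards uses
#' only neural data and measured inputs, never behavior.
#'
#' @param y,z,u training series (T x n matrices; \code{u} may be NULL).
#' @param n1,n2,n3 latent dimensions of the three model sections.
#' @param config a \code{\link{braid_config}}.
#' @return an object of class \code{braid_model}.
#' @export
braid_fit <- function(y, z, u = NULL, n1, n2 = 0L, n3 = 0L,
                      config = braid_config()) {
  y <- as_matrix_ts(y, "y"); z <- as_matrix_ts(z, "z")
  u <- if (is.null(u)) matrix(0, nrow(y), 0L) else as_matrix_ts(u, "u")
  if (nrow(z) != nrow(y) || nrow(u) != nrow(y))
    stop("y, z, u must be aligned")
  if (config$variant != "no_input_ablation" && ncol(u) == 0L &&
      config$variant == "braid" && n3 > 0L)
    stop("stage 3 requires measured inputs (n_u >= 1)")
  if (config$variant == "no_input_ablation") u <- u[, 0L, drop = FALSE]
  horizons <- config$horizons
  sc <- list(y = fit_scaler(y), z = fit_scaler(z, warn_name = "z"),
             u = if (ncol(u) > 0L) fit_scaler(u) else NULL)
  ys <- scale_apply(y, sc$y); zs <- scale_apply(z, sc$z)
  us <- if (ncol(u) > 0L) scale_apply(u, sc$u) else u
  u_feed <- if (config$decoder_input_u && ncol(us) > 0L) us else NULL
  d_ft <- if (is.null(u_feed)) 0L else ncol(us)
  history <- list()

  preprocessor <- NULL
  z_target <- zs
  if (config$preprocess) {
    pp <- preprocess_behavior(y, z, config, n1 = n1)
    preprocessor <- pp$regressor
    z_target <- scale_apply(pp$z_pre, sc$z)
    history$preprocess <- pp$history
  }

  obs1 <- cbind(ys, us)
  sections <- list()

  if (config$variant == "u_braid") {
    # single unsupervised section: all neural dynamics via the neural loss
    specs <- list(A = config$nonlinearity$A, K = config$nonlinearity$K,
                  D = config$nonlinearity$Cy, d_ft = d_ft)
    sec <- with_seed(derive_seed(config$seed, "ub_init"),
                     new_section(n1 + n2, ncol(obs1), ncol(us), ncol(ys),
                                 specs, config$hidden_units,
                                 config$activation))
    sec <- warm_start_section(sec, obs1, us, ys, horizons, ncol(ys),
                              derive_seed(config$seed, "ub_ws"))
    sec <- prefit_decoder(sec, obs1, us, ys, horizons,
                          ctrl_of(config, config$static_epochs),
                          derive_seed(config$seed, "ub_pd"))
    tr <- train_section(sec, obs1, us, ys, horizons, config$hweights,
                        feedthrough = u_feed, control = ctrl_of(config),
                        seed = derive_seed(config$seed, "ub"))
    tr$section <- prefit_decoder(tr$section, obs1, us, ys, horizons,
                                 ctrl_of(config, config$static_epochs),
                                 derive_seed(config$seed, "ub_rf"))
    fsec <- list(sec = tr$section, Cy = tr$section$D, Cz = NULL,
                 role = "unsupervised", inputs = c("y", "u"))
    pc <- pool_chain_targets(fsec, obs1, us, horizons, z_target, u_feed)
    fsec$Cz <- fit_static_map(pc$X, pc$Y, spec_mode(config, "Cz"),
                              control = ctrl_of(config,
                                                config$static_epochs),
                              seed = derive_seed(config$seed, "ub_cz"))
    history$u_braid <- tr$history
    sections$s1 <- fsec
  } else {
    # ---- stage 1: behaviorally relevant dynamics -------------------------
    specs1 <- list(A = config$nonlinearity$A, K = config$nonlinearity$K,
                   D = config$nonlinearity$Cz, d_ft = d_ft)
    sec1 <- with_seed(derive_seed(config$seed, "s1_init"),
                      new_section(n1, ncol(obs1), ncol(us), ncol(zs),
                                  specs1, config$hidden_units,
                                  config$activation))
    sec1 <- warm_start_section(sec1, obs1, us, z_target, horizons,
                               ncol(ys), derive_seed(config$seed, "s1_ws"))
    sec1 <- prefit_decoder(sec1, obs1, us, z_target, horizons,
                           ctrl_of(config, config$static_epochs),
                           derive_seed(config$seed, "s1_pd"))
    tr1 <- train_section(sec1, obs1, us, z_target, horizons,
                         config$hweights, feedthrough = u_feed,
                         control = ctrl_of(config),
                         seed = derive_seed(config$seed, "s1"))
    # final half-step of the alternating scheme: refit the read-out on the
    # trained states
    tr1$section <- prefit_decoder(tr1$section, obs1, us, z_target, horizons,
                                  ctrl_of(config, config$static_epochs),
                                  derive_seed(config$seed, "s1_rf"))
    fsec1 <- list(sec = tr1$section, Cz = tr1$section$D, Cy = NULL,
                  role = "behaviorally_relevant", inputs = c("y", "u"))
    # stage 1b: frozen-state neural read-out
    pc1 <- pool_chain_targets(fsec1, obs1, us, horizons, ys, u_feed)
    fsec1$Cy <- fit_static_map(pc1$X, pc1$Y, spec_mode(config, "Cy"),
                               control = ctrl_of(config,
                                                 config$static_epochs),
                               seed = derive_seed(config$seed, "s1_cy"))
    history$stage1 <- tr1$history
    sections$s1 <- fsec1

    # ---- stage 2: residual neural-specific dynamics ----------------------
    if (n2 > 0L) {
      yhat1 <- section_predict_chain(fsec1, obs1, us, horizons, "Cy", u_feed)
      resid_y <- lapply(yhat1, function(P) {
        R <- ys - P
        R[is.na(R)] <- 0
        R
      })
      XP1 <- attr(yhat1, "XP")
      x1_feed <- rbind(XP1[-1L, , drop = FALSE],
                       matrix(0, 1L, ncol(XP1)))  # x_{k+1|k}, causal at k
      obs2 <- cbind(ys, us, x1_feed)
      specs2 <- list(A = config$nonlinearity$A, K = config$nonlinearity$K,
                     D = config$nonlinearity$Cy, d_ft = d_ft)
      sec2 <- with_seed(derive_seed(config$seed, "s2_init"),
                        new_section(n2, ncol(obs2), ncol(us), ncol(ys),
                                    specs2, config$hidden_units,
                                    config$activation))
      sec2 <- warm_start_section(sec2, obs2, us, resid_y[[1L]], horizons,
                                 ncol(ys),
                                 derive_seed(config$seed, "s2_ws"))
      sec2 <- prefit_decoder(sec2, obs2, us, resid_y, horizons,
                             ctrl_of(config, config$static_epochs),
                             derive_seed(config$seed, "s2_pd"))
      tr2 <- train_section(sec2, obs2, us, resid_y, horizons,
                           config$hweights, feedthrough = u_feed,
                           control = ctrl_of(config),
                           seed = derive_seed(config$seed, "s2"))
      tr2$section <- prefit_decoder(tr2$section, obs2, us, resid_y,
                                    horizons,
                                    ctrl_of(config, config$static_epochs),
                                    derive_seed(config$seed, "s2_rf"))
      fsec2 <- list(sec = tr2$section, Cy = tr2$section$D, Cz = NULL,
                    role = "neural_specific", inputs = c("y", "u", "x1"))
      # stage 2b: frozen-state behavior read-out on the behavior residual
      zhat1 <- section_predict_chain(fsec1, obs1, us, horizons, "Cz", u_feed)
      resid_z <- lapply(zhat1, function(P) {
        R <- z_target - P
        R[is.na(R)] <- 0
        R
      })
      pc2 <- pool_chain_targets(fsec2, obs2, us, horizons, resid_z, u_feed)
      fsec2$Cz <- fit_static_map(pc2$X, pc2$Y, spec_mode(config, "Cz"),
                                 control = ctrl_of(config,
                                                   config$static_epochs),
                                 seed = derive_seed(config$seed, "s2_cz"))
      history$stage2 <- tr2$history
      sections$s2 <- fsec2
    }
  }

  # ---- stage 3: input-driven behavior-specific dynamics ------------------
  if (n3 > 0L) {
    if (ncol(us) == 0L)
      stop("stage 3 is unavailable without measured inputs (n_u = 0)")
    zhat_all <- model_predict_sections(sections, ys, us, horizons, "Cz",
                                       u_feed)
    resid_z3 <- lapply(zhat_all, function(P) {
      R <- zs - P          # actual behavior: stage 3 recovers what
      R[is.na(R)] <- 0     # preprocessing excluded
      R
    })
    specs3 <- list(A = config$nonlinearity$A, K = config$nonlinearity$K,
                   D = config$nonlinearity$Cz, d_ft = d_ft)
    sec3 <- with_seed(derive_seed(config$seed, "s3_init"),
                      new_section(n3, ncol(us), ncol(us), ncol(zs),
                                  specs3, config$hidden_units,
                                  config$activation))
    sec3 <- warm_start_section(sec3, us, us, resid_z3[[1L]], horizons, 0L,
                               derive_seed(config$seed, "s3_ws"))
    sec3 <- prefit_decoder(sec3, us, us, resid_z3, horizons,
                           ctrl_of(config, config$static_epochs),
                           derive_seed(config$seed, "s3_pd"))
    tr3 <- train_section(sec3, us, us, resid_z3, horizons,
                         config$hweights, feedthrough = u_feed,
                         control = ctrl_of(config),
                         seed = derive_seed(config$seed, "s3"))
    tr3$section <- prefit_decoder(tr3$section, us, us, resid_z3, horizons,
                                  ctrl_of(config, config$static_epochs),
                                  derive_seed(config$seed, "s3_rf"))
    sections$s3 <- list(sec = tr3$section, Cz = tr3$section$D, Cy = NULL,
                        role = "behavior_specific", inputs = "u")
    history$stage3 <- tr3$history
  }

  structure(list(sections = sections, scalers = sc,
                 preprocessor = preprocessor,
                 dims = list(n1 = n1, n2 = n2, n3 = n3,
                             n_y = ncol(y), n_z = ncol(z), n_u = ncol(u)),
                 config = config, history = history),
            class = "braid_model")
}

# observation matrix feeding a section's encoder, given scaled signals and
# the stage-1 filtered states
section_obs <- function(fsec, ys, us, XP1 = NULL) {
  if (identical(fsec$inputs, "u")) return(us)
  if ("x1" %in% fsec$inputs) {
    x1_feed <- rbind(XP1[-1L, , drop = FALSE], matrix(0, 1L, ncol(XP1)))
    return(cbind(ys, us, x1_feed))
  }
  cbind(ys, us)
}

# summed read-out predictions over sections; per-horizon T x d with NA heads
model_predict_sections <- function(sections, ys, us, horizons, readout,
                                   u_feed = NULL) {
  T <- nrow(ys)
  XP1 <- NULL
  out <- NULL
  for (fsec in sections) {
    if (is.null(fsec[[readout]])) next
    obs <- section_obs(fsec, ys, us, XP1)
    pr <- section_predict_chain(fsec, obs, us, horizons, readout, u_feed)
    if (fsec$role %in% c("behaviorally_relevant", "unsupervised") &&
        is.null(XP1))
      XP1 <- attr(pr, "XP")
    if (is.null(out)) out <- pr
    else out <- Map(function(a, b) a + b, out, pr)
  }
  if (is.null(XP1) && length(sections) > 0L) {
    # readout absent in stage-1 section: still may need XP1 for later calls
    s1 <- sections[[1L]]
    XP1 <- section_filter(s1$sec, section_obs(s1, ys, us))
  }
  attr(out, "XP1") <- XP1
  out
}

#' Predict neural activity and behavior on new data
#'
#' Filters the predictor-form recursion over the supplied neural and input
#' series, rolls states forward with the generative-form recursion for
#' horizons beyond one step (consuming future inputs but never future neural
#' data), and applies the read-out maps of all fitted sections additively.
#'
#' @param object a fitted \code{braid_model}.
#' @param y,u held-out neural and input series.
#' @param horizons integer vector of steps-ahead to predict.
#' @param ... unused.
#' @return list with per-horizon predicted \code{z} and \code{y} (rows
#'   aligned to the input series; the first m rows of an m-step prediction
#'   are NA), plus the filtered per-section states.
#' @export
predict.braid_model <- function(object, y, u = NULL, horizons = 1L, ...) {
  y <- as_matrix_ts(y, "y")
  u <- if (is.null(u)) matrix(0, nrow(y), 0L) else as_matrix_ts(u, "u")
  check_finite(y, "y"); check_finite(u, "u")
  if (object$dims$n_u > 0L && ncol(u) != object$dims$n_u)
    stop("input dimension mismatch: model expects n_u = ", object$dims$n_u)
  if (object$config$variant == "no_input_ablation") u <- u[, 0L, drop = FALSE]
  sc <- object$scalers
  ys <- scale_apply(y, sc$y)
  us <- if (!is.null(sc$u) && ncol(u) > 0L) scale_apply(u, sc$u) else
    u[, 0L, drop = FALSE]
  u_feed <- if (object$config$decoder_input_u && ncol(us) > 0L) us else NULL
  zp <- model_predict_sections(object$sections, ys, us, horizons, "Cz",
                               u_feed)
  yp <- model_predict_sections(object$sections, ys, us, horizons, "Cy",
                               u_feed)
  list(z = lapply(zp, scale_invert, sc = sc$z),
       y = lapply(yp, scale_invert, sc = sc$y),
       horizons = horizons)
}

#' Filter per-section latent state sequences from observations
#'
#' Runs each section's predictor-form recursion causally over the series:
#' the state at time k depends only on observations up to k-1.
#'
#' @param model a fitted \code{braid_model}.
#' @param y,u neural and input series.
#' @return list of T x n_i state matrices (1-step-ahead predicted states),
#'   one per section.
#' @export
filter_sequence <- function(model, y, u = NULL) {
  y <- as_matrix_ts(y, "y")
  u <- if (is.null(u)) matrix(0, nrow(y), 0L) else as_matrix_ts(u, "u")
  check_finite(y, "y"); check_finite(u, "u")
  if (model$config$variant == "no_input_ablation") u <- u[, 0L, drop = FALSE]
  sc <- model$scalers
  ys <- scale_apply(y, sc$y)
  us <- if (!is.null(sc$u) && ncol(u) > 0L) scale_apply(u, sc$u) else
    u[, 0L, drop = FALSE]
  out <- list()
  XP1 <- NULL
  for (nm in names(model$sections)) {
    fsec <- model$sections[[nm]]
    XP <- section_filter(fsec$sec, section_obs(fsec, ys, us, XP1))
    if (is.null(XP1)) XP1 <- XP
    out[[nm]] <- XP
  }
  out
}

#' One predictor-form update of a section's latent state
#'
#' @param section a fitted section (element of \code{model$sections}) or a
#'   raw internal section object.
#' @param state current state vector (length state_dim).
#' @param observed concatenated section inputs at the current time step.
#' @return the next 1-step-ahead predicted state vector.
#' @export
predictor_step <- function(section, state, observed) {
  sec <- if (!is.null(section$sec)) section$sec else section
  state <- matrix(state, 1L)
  observed <- matrix(observed, 1L)
  if (ncol(state) != sec$state_dim) stop("state dimension mismatch")
  if (ncol(observed) != sec$K$d_in) stop("observation dimension mismatch")
  as.vector(map_apply(sec$A, state) + map_apply(sec$K, observed))
}

#' Roll a 1-step-ahead state forward with the generative-form recursion
#'
#' @param section a fitted section or raw section object.
#' @param state_1step the 1-step-ahead predicted state at k+1|k.
#' @param future_u matrix of the m-1 future inputs u_{k+1}..u_{k+m-1} (may
#'   be NULL for input-free sections or m = 1).
#' @param m prediction horizon; m = 1 returns the state unchanged.
#' @return the m-step-ahead state vector x_{k+m|k}.
#' @export
forecast_rollout <- function(section, state_1step, future_u = NULL, m = 1L) {
  sec <- if (!is.null(section$sec)) section$sec else section
  if (m < 1L) stop("m must be >= 1")
  x <- matrix(state_1step, 1L)
  if (m == 1L) return(as.vector(x))
  needs_u <- !is.null(sec$Kfw)
  if (needs_u) {
    if (is.null(future_u)) stop("future inputs required for m > 1")
    future_u <- as_matrix_ts(future_u, "future_u")
    if (nrow(future_u) < m - 1L)
      stop("future_u must supply m-1 rows")
  }
  for (j in seq_len(m - 1L)) {
    x <- map_apply(sec$Afw, x)
    if (needs_u) x <- x + map_apply(sec$Kfw, future_u[j, , drop = FALSE])
  }
  as.vector(x)
}

#' Linearize a section's generative-form recursion
#'
#' For a linear map returns its matrix directly; for an MLP returns the
#' Jacobian at the origin of the (normalized) state space. Eigenvalues are
#' sorted by modulus descending, then argument.
#'
#' @param section a fitted section (e.g. \code{model$sections$s1}).
#' @return list with the matrix \code{Afw} and its complex
#'   \code{eigenvalues}.
#' @export
linearize_afw <- function(section) {
  sec <- if (!is.null(section$sec)) section$sec else section
  J <- map_jacobian0(sec$Afw)
  list(Afw = J, eigenvalues = sort_eigs(eigen(J, only.values = TRUE)$values))
}

#' @export
print.braid_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf("braid_model (%s): n1=%d n2=%d n3=%d; n_y=%d n_z=%d n_u=%d\n",
              x$config$variant, d$n1, d$n2, d$n3, d$n_y, d$n_z, d$n_u))
  cat(sprintf("  horizons: %s; nonlinearity: A=%s K=%s Cy=%s Cz=%s; %s\n",
              paste(x$config$horizons, collapse = ","),
              x$config$nonlinearity$A, x$config$nonlinearity$K,
              x$config$nonlinearity$Cy, x$config$nonlinearity$Cz,
              if (x$config$preprocess) "preprocessed" else "no preprocessing"))
  invisible(x)
}
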