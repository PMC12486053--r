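#' Specify one of the model's six transformations
#'
#' Each section of the model is built from six maps: the predictor-form
#' recursion \code{A} and encoder \code{K}, the generative-form recursion
#' \code{Afw} and input map \code{Kfw}, and the neural/behavior read-outs
#' \code{Cy}/\code{Cz}. Any map can be an affine (linear) map or a small
#' multi-layer perceptron; this constructor records that choice.
#'
#' @param mode "linear" (affine map) or "nonlinear" (MLP).
#' @param hidden_layers number of hidden layers when nonlinear.
#' @param hidden_units units per hidden layer.
#' @param activation elementwise activation for hidden layers
#'   ("relu" or "tanh").
#' @return an object of class \code{transform_spec}.
#' @export
transform_spec <- function(mode = c("linear", "nonlinear"),
                           hidden_layers = 1L, hidden_units = 64L,
                           activation = c("relu", "tanh")) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  if (mode == "linear") hidden_layers <- 0L
  if (mode == "nonlinear" && hidden_layers < 1L)
    stop("nonlinear mode requires at least one hidden layer")
  structure(list(mode = mode, hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 activation = activation),
            class = "transform_spec")
}

act_fun <- function(x, activation) {
  switch(activation, relu = x * (x > 0), tanh = tanh(x))
}

# activation derivative computed from the *post*-activation values
act_grad_from_post <- function(post, activation) {
  switch(activation,
         relu = (post > 0) * 1,
         tanh = 1 - post * post)
}

# Construct a map with freshly initialized weights. Layout: out = X %*% W + b
# per layer, hidden layers followed by the activation. `init_scale` rescales
# the Glorot init of the output layer; `init_identity` adds 0.5*I to the
# (square) linear read-out so recursion maps start as mild contractions.
new_map <- function(d_in, d_out, spec, init_scale = 1, init_identity = FALSE) {
  if (d_in == 0L) return(NULL)
  dims_in <- c(d_in, rep(spec$hidden_units, spec$hidden_layers))
  dims_out <- c(rep(spec$hidden_units, spec$hidden_layers), d_out)
  nl <- length(dims_in)
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    s <- sqrt(6 / (dims_in[l] + dims_out[l]))
    if (l == nl) s <- s * init_scale
    W <- matrix(stats::runif(dims_in[l] * dims_out[l], -s, s),
                dims_in[l], dims_out[l])
    if (init_identity && l == nl && dims_in[l] == dims_out[l] && nl == 1L)
      W <- W * 0.3 + diag(0.5, d_out)
    layers[[l]] <- list(W = W, b = rep(0, dims_out[l]))
  }
  structure(list(layers = layers, d_in = d_in, d_out = d_out,
                 activation = spec$activation, mode = spec$mode),
            class = "braid_map")
}

# zero-weight copy (used for "null" contributions and gradient accumulators)
map_zero_like <- function(map) {
  map$layers <- lapply(map$layers, function(L)
    list(W = L$W * 0, b = L$b * 0))
  map
}

map_forward <- function(map, X, need_cache = FALSE) {
  nl <- length(map$layers)
  ins <- if (need_cache) vector("list", nl) else NULL
  a <- X
  for (l in seq_len(nl)) {
    if (need_cache) ins[[l]] <- a
    Ly <- map$layers[[l]]
    a <- a %*% Ly$W
    a <- sweep_add_row(a, Ly$b)
    if (l < nl) a <- act_fun(a, map$activation)
  }
  if (need_cache) list(out = a, ins = ins) else list(out = a)
}

map_apply <- function(map, X) map_forward(map, X)$out

# Reverse-mode pass. `dOut` is the loss gradient at the map output for the
# same rows as the cached forward. Returns the gradient list (same shape as
# layers) and, when `need_dx`, the gradient wrt the map input.
map_backward <- function(map, cache, dOut, need_dx = TRUE) {
  nl <- length(map$layers)
  grads <- vector("list", nl)
  d <- dOut
  for (l in rev(seq_len(nl))) {
    In <- cache$ins[[l]]
    grads[[l]] <- list(W = crossprod(In, d), b = colSums(d))
    if (l > 1L || need_dx) {
      d <- d %*% t(map$layers[[l]]$W)
      if (l > 1L) d <- d * act_grad_from_post(In, map$activation)
    }
  }
  list(dX = if (need_dx) d else NULL, grads = grads)
}

sweep_add_row <- function(M, b) {
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

# Jacobian of the map at the origin of its input space (column-vector
# convention: x_out = J %*% x_in). Exact for linear maps; for MLPs it is the
# chain-rule Jacobian evaluated at zero input.
map_jacobian0 <- function(map) {
  nl <- length(map$layers)
  x <- matrix(0, 1, map$d_in)
  J <- diag(map$d_in)
  for (l in seq_len(nl)) {
    Ly <- map$layers[[l]]
    pre <- x %*% Ly$W + matrix(Ly$b, 1)
    J <- t(Ly$W) %*% J
    if (l < nl) {
      # subgradient convention: relu'(0) = 1, so a zero-bias hidden layer
      # passes the affine read-out through rather than vanishing
      g <- switch(map$activation,
                  relu = as.numeric(pre >= 0),
                  tanh = 1 - tanh(pre)^2)
      J <- diag(as.vector(g), nrow = length(g)) %*% J
      x <- act_fun(pre, map$activation)
    }
  }
  J
}

map_params <- function(map) map$layers

map_set_params <- function(map, params) {
  map$layers <- params
  map
}
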