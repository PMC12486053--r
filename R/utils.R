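# Internal numerical utilities shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps every
# source of randomness a pure function of the user-facing seed.
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream))) %% 10000L
  as.integer((as.numeric(seed) * 10007 + s * 97) %% 2147483562)
}

spectral_radius <- function(A) {
  if (length(A) == 0L) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Stationary covariance P solving P = A P A' + Q (discrete Lyapunov),
# via the Kronecker-product linear system; fine for the small state
# dimensions used here.
dlyap <- function(A, Q) {
  n <- nrow(A)
  M <- diag(n * n) - kronecker(A, A)
  matrix(solve(M, as.vector(Q)), n, n)
}

# All permutations of 1..n (n small); used for optimal eigenvalue matching.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

as_matrix_ts <- function(x, name) {
  if (is.null(x)) return(NULL)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(name, " must be numeric")
  storage.mode(x) <- "double"
  x
}

check_finite <- function(x, name) {
  if (!is.null(x) && !all(is.finite(x)))
    stop("non-finite values in ", name)
  invisible(TRUE)
}

# elementwise binary op over nested lists of arrays (same shape)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map1 <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map1(f, a[[i]])
    out
  } else {
    f(a)
  }
}
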