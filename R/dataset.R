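#' Construct an aligned neural-behavioral-input dataset
#'
#' Bundles a neural time series \code{y} (T x n_y), a behavior time series
#' \code{z} (T x n_z) and a measured-input time series \code{u} (T x n_u)
#' recorded at a common sampling period, together with contiguous
#' cross-validation fold assignments.
#'
#' @param y,z,u numeric matrices (or vectors) with one row per time sample.
#'   \code{u} may be \code{NULL} when no input was measured.
#' @param dt sampling period in seconds.
#' @param n_folds number of contiguous cross-validation folds used when
#'   \code{fold_ids} is not given.
#' @param fold_ids optional integer vector of per-sample fold labels; must
#'   partition the samples into contiguous blocks.
#' @param seed generator seed recorded for provenance (may be NA for real
#'   data).
#' @return an object of class \code{braid_dataset}.
#' @export
braid_dataset <- function(y, z, u = NULL, dt = 1, n_folds = 2L,
                          fold_ids = NULL, seed = NA_integer_) {
  y <- as_matrix_ts(y, "y")
  z <- as_matrix_ts(z, "z")
  u <- if (is.null(u)) matrix(0, nrow(y), 0L) else as_matrix_ts(u, "u")
  T <- nrow(y)
  if (nrow(z) != T || nrow(u) != T)
    stop("y, z and u must have the same number of samples")
  check_finite(y, "y"); check_finite(z, "z"); check_finite(u, "u")
  if (is.null(fold_ids)) {
    fold_ids <- rep(seq_len(n_folds), each = ceiling(T / n_folds))[seq_len(T)]
  } else {
    if (length(fold_ids) != T) stop("fold_ids must have one entry per sample")
    if (any(diff(fold_ids) < 0) && any(duplicated(rle(fold_ids)$values)))
      stop("fold_ids must form contiguous blocks")
  }
  structure(list(y = y, z = z, u = u, dt = dt,
                 fold_ids = as.integer(fold_ids),
                 seed = seed),
            class = "braid_dataset")
}

#' @export
print.braid_dataset <- function(x, ...) {
  cat(sprintf(
    "braid_dataset: T=%d samples (dt=%g s), n_y=%d, n_z=%d, n_u=%d, %d folds\n",
    nrow(x$y), x$dt, ncol(x$y), ncol(x$z), ncol(x$u),
    length(unique(x$fold_ids))))
  invisible(x)
}

#' @export
dim.braid_dataset <- function(x) c(nrow(x$y), ncol(x$y), ncol(x$z), ncol(x$u))

# train/test split by fold
split_folds <- function(dataset, test_fold) {
  te <- dataset$fold_ids == test_fold
  list(train = lapply(dataset[c("y", "z", "u")],
                      function(m) m[!te, , drop = FALSE]),
       test = lapply(dataset[c("y", "z", "u")],
                     function(m) m[te, , drop = FALSE]))
}
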