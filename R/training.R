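#' Weighted multi-horizon mean-squared-error loss
#'
#' Sums per-horizon mean-squared errors between m-step-ahead predictions and
#' the target series, weighted per horizon (default weights all 1, the plain
#' sum).
#'
#' @param predictions list with one prediction series per horizon. A series
#'   may either be aligned to the target rows (with NA in the first m rows,
#'   as returned by \code{\link{predict.braid_model}}) or have
#'   \code{T - m} rows, in which case row k is compared to target row k+m.
#' @param targets the target series (T x n matrix or vector).
#' @param horizons integer vector of horizons, one per prediction series.
#' @param weights per-horizon loss weights.
#' @return scalar loss.
#' @export
loss_mstep <- function(predictions, targets, horizons = seq_along(predictions),
                       weights = rep(1, length(predictions))) {
  targets <- as_matrix_ts(targets, "targets")
  if (length(predictions) != length(horizons) ||
      length(weights) != length(horizons))
    stop("predictions, horizons and weights must have equal length")
  T <- nrow(targets)
  total <- 0
  for (i in seq_along(predictions)) {
    P <- as_matrix_ts(predictions[[i]], "prediction")
    m <- horizons[i]
    if (nrow(P) == T) {
      keep <- stats::complete.cases(P)
      err <- P[keep, , drop = FALSE] - targets[keep, , drop = FALSE]
    } else if (nrow(P) == T - m) {
      err <- P - targets[(m + 1L):T, , drop = FALSE]
    } else {
      stop("prediction series for horizon ", m,
           " has incompatible length")
    }
    total <- total + weights[i] * mean(err^2)
  }
  total
}

#' Automatic per-map nonlinearity selection
#'
#' Fits one stage-1 model for every linear/nonlinear assignment over the
#' four maps A, K, Cy, Cz (the generative-form maps inherit the modes of A
#' and K), scores each candidate by its behavior decoding correlation, and
#' returns the best assignment. Scoring uses the training data itself by
#' default; \code{select_on = "validation"} scores on a held-out tail of the
#' training series instead. Candidates are ordered by their number of
#' nonlinear maps, so ties break toward the simpler model. Candidates that
#' fail to train are excluded with a warning; an error is raised only if all
#' fail.
#'
#' @param y,z,u training series.
#' @param n1 stage-1 latent dimension.
#' @param config base \code{\link{braid_config}} (its nonlinearity entry is
#'   overridden per candidate).
#' @param maps_grid which maps to switch; default all four.
#' @param select_on "train" or "validation".
#' @param val_frac fraction of samples held out when scoring on validation.
#' @return list with \code{assignment} (named list of modes), \code{model}
#'   (the fitted winning model), and \code{scores} (a data.frame over
#'   candidates).
#' @export
auto_select_nonlinearity <- function(y, z, u = NULL, n1,
                                     config = braid_config(),
                                     maps_grid = c("A", "K", "Cy", "Cz"),
                                     select_on = c("train", "validation"),
                                     val_frac = 0.2) {
  select_on <- match.arg(select_on)
  y <- as_matrix_ts(y, "y"); z <- as_matrix_ts(z, "z")
  u <- if (is.null(u)) matrix(0, nrow(y), 0L) else as_matrix_ts(u, "u")
  grid <- expand.grid(rep(list(c("linear", "nonlinear")),
                          length(maps_grid)), stringsAsFactors = FALSE)
  names(grid) <- maps_grid
  n_nl <- rowSums(grid == "nonlinear")
  grid <- grid[order(n_nl), , drop = FALSE]
  if (select_on == "validation") {
    T <- nrow(y)
    n_va <- max(2L, round(val_frac * T))
    tr <- seq_len(T - n_va); va <- (T - n_va + 1L):T
  } else {
    tr <- seq_len(nrow(y)); va <- tr
  }
  best_cc <- -Inf; best_model <- NULL; best_assign <- NULL
  scores <- data.frame()
  for (r in seq_len(nrow(grid))) {
    assign <- utils::modifyList(config$nonlinearity,
                                as.list(grid[r, , drop = FALSE]))
    cfg <- config
    cfg$nonlinearity <- assign
    cc <- tryCatch({
      fit <- braid_fit(y[tr, , drop = FALSE], z[tr, , drop = FALSE],
                       u[tr, , drop = FALSE], n1 = n1, config = cfg)
      pr <- predict(fit, y[va, , drop = FALSE], u[va, , drop = FALSE],
                    horizons = 1L)
      val <- metric_cc(pr$z[[1L]], z[va, , drop = FALSE])
      if (val > best_cc) {
        best_cc <- val; best_model <- fit; best_assign <- assign
      }
      val
    }, error = function(e) {
      warning("candidate ", paste0(names(assign), "=",
                                   unlist(assign), collapse = ","),
              " failed: ", conditionMessage(e))
      NA_real_
    })
    scores <- rbind(scores,
                    cbind(grid[r, , drop = FALSE],
                          data.frame(cc_z = cc, n_nonlinear = sum(
                            grid[r, ] == "nonlinear"))))
  }
  if (is.null(best_model)) stop("all nonlinearity candidates failed")
  rownames(scores) <- NULL
  list(assignment = best_assign, model = best_model, scores = scores)
}
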