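# Cross-validated evaluation: prediction metrics per horizon, recovery of
# the intrinsic-dynamics eigenvalues, forecasting curves, and report
# aggregation.

#' Dimension-averaged Pearson correlation between prediction and truth
#'
#' Computes the Pearson correlation per channel between aligned rows of the
#' predicted and actual series (rows with NA in either are dropped) and
#' averages across channels. Zero-variance channels are excluded with a
#' warning; if all channels are degenerate an error is raised.
#'
#' @param pred,truth numeric matrices or vectors of equal length.
#' @return scalar mean correlation.
#' @export
metric_cc <- function(pred, truth) {
  m <- metric_channels(pred, truth, check_pred = TRUE)
  vals <- mapply(function(p, t) stats::cor(p, t), m$pred, m$truth)
  mean(vals)
}

#' Dimension-averaged coefficient of determination
#'
#' One minus the ratio of residual to total sum of squares per channel,
#' averaged across channels; can be negative for predictions worse than the
#' mean.
#'
#' @inheritParams metric_cc
#' @return scalar mean R-squared.
#' @export
metric_r2 <- function(pred, truth) {
  m <- metric_channels(pred, truth)
  vals <- mapply(function(p, t) {
    1 - sum((t - p)^2) / sum((t - mean(t))^2)
  }, m$pred, m$truth)
  mean(vals)
}

metric_channels <- function(pred, truth, check_pred = FALSE) {
  pred <- as_matrix_ts(pred, "pred")
  truth <- as_matrix_ts(truth, "truth")
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical dimensions")
  keep <- stats::complete.cases(pred) & stats::complete.cases(truth)
  if (sum(keep) < 2L) stop("need at least 2 aligned samples")
  pred <- pred[keep, , drop = FALSE]
  truth <- truth[keep, , drop = FALSE]
  ok <- apply(truth, 2L, stats::sd) > 1e-12
  if (check_pred)  # correlation is undefined for a constant prediction too
    ok <- ok & apply(pred, 2L, stats::sd) > 1e-12
  if (!any(ok)) stop("metric undefined: all channels have zero variance")
  if (!all(ok)) warning("excluding zero-variance channel(s) from metric")
  list(pred = lapply(which(ok), function(j) pred[, j]),
       truth = lapply(which(ok), function(j) truth[, j]))
}

#' Normalized optimal-assignment distance between eigenvalue sets
#'
#' Matches the two sets one-to-one so as to minimize the total distance in
#' the complex plane (exhaustive assignment for up to 8 eigenvalues, a
#' 2-opt-refined greedy assignment beyond), then returns the mean matched
#' distance normalized by the mean modulus of the true eigenvalues. The
#' result is invariant to ordering and zero iff the sets are equal.
#'
#' @param true_eigs,learned_eigs complex vectors of equal length.
#' @return scalar normalized error.
#' @export
eigenvalue_error <- function(true_eigs, learned_eigs) {
  n <- length(true_eigs)
  if (length(learned_eigs) != n)
    stop("eigenvalue sets must have equal cardinality ",
         "(fit the model at the true state dimension)")
  D <- outer(true_eigs, learned_eigs,
             function(a, b) Mod(a - b))
  if (n <= 8L) {
    best <- Inf
    for (p in all_permutations(n)) {
      tot <- sum(D[cbind(seq_len(n), p)])
      if (tot < best) best <- tot
    }
  } else {
    p <- integer(n)
    free <- seq_len(n)
    for (i in seq_len(n)) {
      j <- free[which.min(D[i, free])]
      p[i] <- j
      free <- setdiff(free, j)
    }
    repeat {
      improved <- FALSE
      for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
        cur <- D[i, p[i]] + D[k, p[k]]
        alt <- D[i, p[k]] + D[k, p[i]]
        if (alt < cur - 1e-15) {
          tmp <- p[i]; p[i] <- p[k]; p[k] <- tmp
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    best <- sum(D[cbind(seq_len(n), p)])
  }
  (best / n) / mean(Mod(true_eigs))
}

#' Prediction accuracy as a function of forecasting horizon
#'
#' For each horizon m, predicts held-out behavior and neural data via the
#' filter plus generative-form rollout (consuming future inputs but no
#' future neural data) and computes the requested metric.
#'
#' @param model a fitted \code{braid_model}.
#' @param y,u,z held-out series.
#' @param horizons horizons to evaluate (default 1:32).
#' @return data.frame with columns horizon, cc_z, r2_z, cc_y, r2_y. Horizons
#'   whose rollout diverges yield NaN entries rather than being dropped.
#' @export
forecast_curve <- function(model, y, u = NULL, z, horizons = 1:32) {
  pr <- predict(model, y, u, horizons = horizons)
  one <- function(P, truth) {
    if (is.null(P) || !all(is.finite(P[stats::complete.cases(P), ])))
      return(c(NaN, NaN))
    c(metric_cc(P, truth), metric_r2(P, truth))
  }
  res <- t(vapply(seq_along(horizons), function(i) {
    c(one(pr$z[[i]], z), one(pr$y[[i]], y))
  }, numeric(4)))
  data.frame(horizon = horizons, cc_z = res[, 1], r2_z = res[, 2],
             cc_y = res[, 3], r2_y = res[, 4])
}

#' Cross-validated fitting and evaluation
#'
#' For each contiguous fold of the dataset, fits the model on the remaining
#' folds and evaluates predictions on the held-out fold, then aggregates
#' fold-level metrics as mean and standard error across runs.
#'
#' @param dataset a \code{braid_dataset}.
#' @param n1,n2,n3 latent dimensions per section.
#' @param config a \code{\link{braid_config}}.
#' @param eval_horizons horizons at which held-out metrics are reported.
#' @param keep_models if TRUE, fold models are returned in the report.
#' @return an object of class \code{braid_eval_report}: fold-level metric
#'   rows, their mean +/- s.e.m., and metadata.
#' @export
cross_validate <- function(dataset, n1, n2 = 0L, n3 = 0L,
                           config = braid_config(), eval_horizons = 1L,
                           keep_models = FALSE) {
  folds <- sort(unique(dataset$fold_ids))
  if (length(folds) < 2L) stop("need at least 2 folds")
  min_len <- min(table(dataset$fold_ids))
  if (min_len <= max(c(eval_horizons, config$horizons)) + 1L)
    stop("fold too short for the longest horizon")
  rows <- list()
  models <- list()
  for (f in folds) {
    sp <- split_folds(dataset, f)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    fit <- braid_fit(sp$train$y, sp$train$z, sp$train$u,
                     n1 = n1, n2 = n2, n3 = n3, config = cfg)
    pr <- predict(fit, sp$test$y, sp$test$u, horizons = eval_horizons)
    for (i in seq_along(eval_horizons)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, horizon = eval_horizons[i],
        cc_z = metric_cc(pr$z[[i]], sp$test$z),
        r2_z = metric_r2(pr$z[[i]], sp$test$z),
        cc_y = metric_cc(pr$y[[i]], sp$test$y),
        r2_y = metric_r2(pr$y[[i]], sp$test$y))
    }
    if (keep_models) models[[as.character(f)]] <- fit
  }
  fold_metrics <- do.call(rbind, rows)
  structure(list(fold_metrics = fold_metrics,
                 summary = summarize_metrics(fold_metrics),
                 metadata = list(variant = config$variant,
                                 dims = list(n1 = n1, n2 = n2, n3 = n3),
                                 seed = config$seed,
                                 nonlinearity = config$nonlinearity),
                 models = if (keep_models) models),
            class = "braid_eval_report")
}

# mean and s.e.m. per horizon across runs (folds, or folds x datasets)
summarize_metrics <- function(fold_metrics) {
  metrics <- c("cc_z", "r2_z", "cc_y", "r2_y")
  out <- lapply(split(fold_metrics, fold_metrics$horizon), function(df) {
    means <- colMeans(df[metrics])
    sems <- apply(df[metrics], 2L, stats::sd) / sqrt(nrow(df))
    data.frame(horizon = df$horizon[1L], n_runs = nrow(df),
               metric = metrics, mean = as.numeric(means),
               sem = as.numeric(sems), row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pool fold-level metrics across several evaluation reports
#'
#' @param reports list of \code{braid_eval_report} objects (e.g. one per
#'   simulated system); fold-level rows are pooled and re-aggregated so the
#'   s.e.m. is across all runs.
#' @return a \code{braid_eval_report} without models.
#' @export
pool_reports <- function(reports) {
  fm <- do.call(rbind, lapply(seq_along(reports), function(i) {
    df <- reports[[i]]$fold_metrics
    df$dataset <- i
    df
  }))
  structure(list(fold_metrics = fm, summary = summarize_metrics(fm),
                 metadata = reports[[1L]]$metadata, models = NULL),
            class = "braid_eval_report")
}

#' @export
print.braid_eval_report <- function(x, ...) {
  cat("braid_eval_report (", x$metadata$variant, "), ",
      max(x$summary$n_runs), " runs\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
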