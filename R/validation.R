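#' Random k-fold partition
#'
#' @param n Number of observations.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:k`; fold sizes differ by at
#'   most one.
#' @export
kfold_split <- function(n, k, seed = 1) {
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validation metrics
#'
#' The four held-out prediction metrics used to validate the spatial model:
#' Pearson correlation `cov(p_hat, p) / (sd(p_hat) sd(p))`, root mean
#' squared error, mean absolute error, and percentage bias
#' `100 * sum(p_hat - p) / sum(p)`.
#'
#' @param p_hat Predicted values.
#' @param p Observed values (held-out cluster proportions `y/m`).
#' @return A scalar; `metric_pearson` returns `NA` (with a warning) for
#'   zero-variance input, as does `metric_pct_bias` when `sum(p) == 0`.
#' @export
metric_pearson <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p), length(p) >= 2)
  if (stats::sd(p_hat) == 0 || stats::sd(p) == 0) {
    warning("zero-variance vector: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cov(p_hat, p) / (stats::sd(p_hat) * stats::sd(p))
}

#' @rdname metric_pearson
#' @export
metric_rmse <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p))
  sqrt(mean((p_hat - p)^2))
}

#' @rdname metric_pearson
#' @export
metric_mae <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p))
  mean(abs(p_hat - p))
}

#' @rdname metric_pearson
#' @export
metric_pct_bias <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p))
  if (sum(p) == 0) {
    warning("sum of observed values is zero: percentage bias undefined")
    return(NA_real_)
  }
  100 * sum(p_hat - p) / sum(p)
}

cv_metric_row <- function(p_hat, p) {
  data.frame(rho = suppressWarnings(metric_pearson(p_hat, p)),
             rmse = metric_rmse(p_hat, p),
             mae = metric_mae(p_hat, p),
             pct_bias = suppressWarnings(metric_pct_bias(p_hat, p)))
}

#' k-fold cross-validation of the spatial binomial model
#'
#' Repeatedly refits the full spatial model on `k - 1` folds, predicts the
#' posterior mean prevalence at the held-out cluster locations, and scores
#' the predictions against the held-out empirical proportions `y/m` with
#' the four metrics of [metric_pearson()]. Folds whose fit fails are
#' flagged and excluded from the pooled metrics with a warning.
#'
#' @param clusters Cluster data frame (as for [fit_spatial_binomial()]).
#' @param selected_covariates Covariate column names.
#' @param priors A [default_priors()] object.
#' @param k Number of folds (default 5).
#' @param config An [inference_config()]; its seed also drives the fold
#'   split and the per-fold prediction draws.
#' @param n_draws Posterior draws per held-out prediction.
#' @return An object of class `cv_result`: list with `k`, `per_fold` (data
#'   frame: fold, n_test, rho, rmse, mae, pct_bias, ok), `pooled` (metrics
#'   over all held-out predictions), `predictions` (data frame of held-out
#'   index, observed, predicted), and `seed`.
#' @export
cross_validate <- function(clusters, selected_covariates, priors, k = 5,
                           config = inference_config(), n_draws = 100) {
  n <- nrow(clusters)
  folds <- kfold_split(n, k, seed = config$seed)
  obs_all <- clusters$y_events / clusters$m
  per_fold <- NULL
  pred_all <- rep(NA_real_, n)
  ok_all <- rep(TRUE, n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- tryCatch(
      fit_spatial_binomial(clusters[train, , drop = FALSE],
                           selected_covariates, priors, config),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", f, " failed to fit: ", conditionMessage(fit))
      per_fold <- rbind(per_fold, data.frame(
        fold = f, n_test = length(test), rho = NA_real_, rmse = NA_real_,
        mae = NA_real_, pct_bias = NA_real_, ok = FALSE))
      ok_all[test] <- FALSE
      next
    }
    X_new <- cbind(1, as.matrix(
      clusters[test, selected_covariates, drop = FALSE]))
    locs_new <- if (config$use_locations == "reported")
      cbind(clusters$x[test], clusters$y[test])
    else cbind(clusters$x_true[test], clusters$y_true[test])
    pr <- predict_at_points(fit, X_new, locs_new, n_draws = n_draws,
                            seed = config$seed + f)
    pred_all[test] <- pr$mean
    per_fold <- rbind(per_fold, cbind(
      data.frame(fold = f, n_test = length(test)),
      cv_metric_row(pr$mean, obs_all[test]),
      data.frame(ok = TRUE)))
  }
  use <- ok_all & !is.na(pred_all)
  pooled <- cv_metric_row(pred_all[use], obs_all[use])
  structure(list(k = k, per_fold = per_fold, pooled = pooled,
                 predictions = data.frame(index = which(use),
                                          observed = obs_all[use],
                                          predicted = pred_all[use]),
                 seed = config$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d held-out predictions)\n",
              x$k, nrow(x$predictions)))
  print(x$per_fold, digits = 3)
  cat("pooled:\n")
  print(x$pooled, digits = 3)
  invisible(x)
}
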