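#' Pearson correlation matrix of candidate covariates
#'
#' @param X Numeric matrix, one column per covariate, >= 2 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 observations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(X)))
    stop("constant column(s): ", paste(nm[sds == 0], collapse = ", "))
  }
  stats::cor(X)
}

#' Flag collinear covariate pairs
#'
#' Pairs whose absolute Pearson correlation exceeds the threshold (0.8 by
#' default). Absolute correlation is used because strong negative
#' collinearity is as harmful as positive.
#'
#' @param R Correlation matrix.
#' @param threshold Flagging threshold on `|r|`.
#' @return Data frame with columns `i`, `j` (`i < j`) and `r`.
#' @export
flag_collinear_pairs <- function(R, threshold = 0.8) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  idx <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], r = R[idx])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial GLM fit for covariate screening
#'
#' Maximum-likelihood binomial GLM (logit link) fitted by iteratively
#' reweighted least squares via [stats::glm()]. Non-convergence or
#' separation (diverging coefficients / boundary fitted probabilities) is
#' flagged, never silent.
#'
#' @param X Covariate matrix (no intercept column; one is added).
#' @param y Event counts per cluster.
#' @param m Trials per cluster.
#' @return An object of class `glm_fit`: list with `coefficients`,
#'   `log_likelihood`, `n_obs` (clusters), `n_params`, `converged`, and the
#'   underlying `glm` object.
#' @export
fit_binomial_glm <- function(X, y, m) {
  if (any(y < 0) || any(y > m)) stop("need 0 <= y <= m elementwise")
  df <- if (is.null(X) || NCOL(X) == 0) data.frame(row.names = seq_along(y))
        else as.data.frame(X)
  fml <- if (ncol(df) == 0) cbind(y, m - y) ~ 1
         else stats::as.formula(paste("cbind(y, m - y) ~",
                                      paste(sprintf("`%s`", names(df)),
                                            collapse = " + ")))
  df$y <- y; df$m <- m
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) invokeRestart("muffleWarning"))
  mu <- stats::fitted(fit)
  separated <- any(abs(stats::coef(fit)) > 15) ||
    any(mu < 1e-8) || any(mu > 1 - 1e-8)
  converged <- fit$converged && !separated && all(is.finite(stats::coef(fit)))
  if (!converged)
    warning("binomial GLM did not converge cleanly (possible separation)")
  structure(list(coefficients = stats::coef(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_obs = length(y),
                 n_params = length(stats::coef(fit)),
                 converged = converged,
                 glm = fit),
            class = "glm_fit")
}

#' Bayesian information criterion of a screening fit
#'
#' `BIC = -2 log L + p log(n)`, with `n` the number of clusters (the
#' modelled observational units), not the number of Bernoulli trials.
#'
#' @param fit A `glm_fit`.
#' @return Scalar BIC.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!fit$converged) stop("BIC requested for an unconverged fit")
  -2 * fit$log_likelihood + fit$n_params * log(fit$n_obs)
}

#' Resolve flagged collinear pairs by single-covariate BIC
#'
#' Each covariate appearing in a flagged pair is fitted individually
#' (intercept plus that covariate) in a binomial GLM; within each pair the
#' lower-BIC member is retained and the other omitted. A covariate omitted
#' in any pair stays omitted. BIC ties are broken deterministically in
#' favour of the lower column index, with a warning.
#'
#' @param X Covariate matrix.
#' @param y,m Event counts and trials.
#' @param flagged_pairs Data frame from [flag_collinear_pairs()].
#' @return Integer vector of retained column indices.
#' @export
resolve_collinear <- function(X, y, m, flagged_pairs) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(flagged_pairs) || nrow(flagged_pairs) == 0)
    return(seq_len(p))
  involved <- sort(unique(c(flagged_pairs$i, flagged_pairs$j)))
  bics <- stats::setNames(rep(NA_real_, p), seq_len(p))
  for (j in involved)
    bics[j] <- bic(fit_binomial_glm(X[, j, drop = FALSE], y, m))
  dropped <- logical(p)
  for (r in seq_len(nrow(flagged_pairs))) {
    i <- flagged_pairs$i[r]; j <- flagged_pairs$j[r]
    if (bics[i] == bics[j]) {
      warning("BIC tie between covariates ", i, " and ", j,
              "; retaining the lower index")
      dropped[j] <- TRUE
    } else if (bics[i] < bics[j]) dropped[j] <- TRUE else dropped[i] <- TRUE
  }
  which(!dropped)
}

#' Iterative variance-inflation-factor filter
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of covariate
#' `j` on the others. While any VIF exceeds the threshold (4 by default),
#' the covariate with the largest VIF is removed; perfectly collinear
#' covariates (infinite VIF) are removed first.
#'
#' @param X Covariate matrix (>= 2 columns to do anything).
#' @param threshold VIF threshold.
#' @return Integer vector of retained column indices.
#' @export
vif_filter <- function(X, threshold = 4) {
  X <- as.matrix(X)
  keep <- seq_len(ncol(X))
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(seq_along(keep), function(jj) {
      yj <- X[, keep[jj]]
      Xo <- X[, keep[-jj], drop = FALSE]
      # near-perfect fits are expected here; they signal infinite VIF
      r2 <- suppressWarnings(summary(stats::lm(yj ~ Xo))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    if (all(vifs <= threshold)) break
    worst <- which.max(vifs)
    if (!is.finite(vifs[worst]))
      message("removing perfectly collinear covariate ", keep[worst])
    keep <- keep[-worst]
  }
  keep
}

#' Compute all variance inflation factors
#'
#' @param X Covariate matrix with >= 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
vif_values <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

#' Backward stepwise covariate selection by BIC
#'
#' Starting from the model with all remaining covariates, each iteration
#' tries removing every covariate in turn and adopts the single removal
#' with the lowest BIC, provided it improves on the current model's BIC;
#' the search stops when no removal lowers the BIC. The intercept is never
#' removed. The final model is therefore locally optimal: no
#' single-covariate removal lowers its BIC.
#'
#' @param X Covariate matrix, already screened for collinearity.
#' @param y,m Event counts and trials.
#' @return An object of class `selection_trace`: list with `final_set`
#'   (retained column indices), `stepwise_path` (data frame: removed
#'   covariate, BIC before and after each adopted removal), and `final_bic`.
#' @export
backward_select <- function(X, y, m) {
  X <- as.matrix(X)
  current <- seq_len(ncol(X))
  fit_set <- function(set)
    bic(fit_binomial_glm(if (length(set)) X[, set, drop = FALSE] else NULL,
                         y, m))
  bic_cur <- fit_set(current)
  path <- data.frame(removed = integer(), bic_before = numeric(),
                     bic_after = numeric())
  while (length(current) > 0) {
    cand <- vapply(seq_along(current),
                   function(jj) fit_set(current[-jj]), 0)
    best <- which.min(cand)
    if (cand[best] >= bic_cur) break
    path <- rbind(path, data.frame(removed = current[best],
                                   bic_before = bic_cur,
                                   bic_after = cand[best]))
    current <- current[-best]
    bic_cur <- cand[best]
  }
  structure(list(final_set = current, stepwise_path = path,
                 final_bic = bic_cur),
            class = "selection_trace")
}

#' Two-stage covariate selection pipeline
#'
#' Runs the full procedure: flag pairs with `|r| > 0.8` from the Pearson
#' matrix, resolve each flagged pair by single-covariate BIC, drop
#' covariates with `VIF > 4` (iteratively worst-first), then backward-BIC
#' stepwise selection. Deterministic given the data.
#'
#' @param X Covariate matrix with named columns.
#' @param y,m Event counts and trials.
#' @param r_threshold Correlation flagging threshold.
#' @param vif_threshold VIF threshold.
#' @return An object of class `selection_trace` with elements
#'   `flagged_pairs`, `dropped_by_bic`, `dropped_by_vif`, `stepwise_path`,
#'   `final_set` (column indices into `X`), `final_names`, `final_bic`.
#' @export
select_covariates <- function(X, y, m, r_threshold = 0.8,
                              vif_threshold = 4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov_", seq_len(ncol(X)))
  R <- pearson_matrix(X)
  flagged <- flag_collinear_pairs(R, r_threshold)
  keep1 <- resolve_collinear(X, y, m, flagged)
  dropped_bic <- setdiff(seq_len(ncol(X)), keep1)
  X1 <- X[, keep1, drop = FALSE]
  keep2_local <- if (ncol(X1) >= 2) vif_filter(X1, vif_threshold)
                 else seq_len(ncol(X1))
  keep2 <- keep1[keep2_local]
  dropped_vif <- setdiff(keep1, keep2)
  X2 <- X[, keep2, drop = FALSE]
  bw <- backward_select(X2, y, m)
  final <- keep2[bw$final_set]
  path <- bw$stepwise_path
  if (nrow(path)) path$removed <- keep2[path$removed]
  structure(list(flagged_pairs = flagged,
                 dropped_by_bic = dropped_bic,
                 dropped_by_vif = dropped_vif,
                 stepwise_path = path,
                 final_set = final,
                 final_names = colnames(X)[final],
                 final_bic = bw$final_bic),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("covariate selection trace\n")
  if (!is.null(x$flagged_pairs))
    cat("  flagged pairs (|r| > threshold):", nrow(x$flagged_pairs), "\n")
  if (!is.null(x$dropped_by_bic))
    cat("  dropped by pairwise BIC:",
        if (length(x$dropped_by_bic)) paste(x$dropped_by_bic, collapse = ", ")
        else "none", "\n")
  if (!is.null(x$dropped_by_vif))
    cat("  dropped by VIF:",
        if (length(x$dropped_by_vif)) paste(x$dropped_by_vif, collapse = ", ")
        else "none", "\n")
  cat("  stepwise removals:", nrow(x$stepwise_path), "\n")
  cat("  final set:",
      if (length(x$final_set)) paste(x$final_set, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}
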