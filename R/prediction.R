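#' Aggregate a grid to a coarser resolution by block means
#'
#' Averages `factor x factor` windows of cells, ignoring missing cells;
#' blocks that are entirely missing stay missing. Partial blocks at the
#' south/east edges are averaged over the cells they contain. Used to take
#' native 1 km covariate layers to the 5 km modelling resolution.
#'
#' @param grid A `covariate_grid`.
#' @param factor Integer aggregation factor (>= 1).
#' @return A `covariate_grid` at `factor * cell` resolution, same origin.
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "covariate_grid"))
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nro <- ceiling(nr / factor); nco <- ceiling(nc / factor)
  ri <- rep(seq_len(nro), each = factor)[seq_len(nr)]
  ci <- rep(seq_len(nco), each = factor)[seq_len(nc)]
  grp <- outer(ri, ci, function(a, b) (b - 1L) * nro + a)
  sums <- rowsum(as.vector(v) * !is.na(as.vector(v)), as.vector(grp),
                 na.rm = TRUE)
  cnts <- rowsum(as.numeric(!is.na(as.vector(v))), as.vector(grp))
  out <- rep(NA_real_, nro * nco)
  ok <- cnts[, 1] > 0
  out[as.integer(rownames(sums))[ok]] <- sums[ok, 1] / cnts[ok, 1]
  vals <- matrix(out, nro, nco)
  # origin: the coarse grid is anchored at the grid's north-west corner, so
  # partial blocks sit at the south/east edges and ymin shifts accordingly
  covariate_grid(vals, xmin = grid$xmin,
                 ymin = grid_ymax(grid) - nro * factor * grid$cell,
                 cell = factor * grid$cell, name = grid$name)
}

#' Extract grid values at point locations
#'
#' Returns the value of the cell containing each point, one column per grid.
#' Cell ownership is half-open: a point on the shared edge of two cells
#' belongs to the cell to its east (larger x) or south (smaller y), making
#' the extraction bit-reproducible.
#'
#' @param grids A `covariate_grid` or list of them.
#' @param points Two-column matrix of (x, y) planar-km coordinates.
#' @return Numeric matrix, one row per point and one named column per grid.
#' @export
extract_at_points <- function(grids, points) {
  if (inherits(grids, "covariate_grid")) grids <- list(grids)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  out <- matrix(NA_real_, nrow(points), length(grids))
  nms <- vapply(seq_along(grids), function(i) {
    nm <- names(grids)[i]
    if (!is.null(nm) && nzchar(nm)) nm else grids[[i]]$name
  }, "")
  colnames(out) <- nms
  for (g in seq_along(grids)) {
    grid <- grids[[g]]
    nr <- nrow(grid$values); nc <- ncol(grid$values)
    j <- floor((points[, 1] - grid$xmin) / grid$cell) + 1
    i <- floor((grid_ymax(grid) - points[, 2]) / grid$cell) + 1
    # points exactly on the north/west outer boundary belong to the first
    # row/column (half-open rule applied inward at the grid edge)
    i[points[, 2] == grid_ymax(grid)] <- 1
    j[points[, 1] == grid$xmin] <- 1
    bad <- i < 1 | i > nr | j < 1 | j > nc | !is.finite(i) | !is.finite(j)
    if (any(bad))
      stop("point(s) outside grid bounds: rows ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    out[, g] <- grid$values[cbind(i, j)]
  }
  out
}

#' Conditional moments of the spatial field at new locations
#'
#' Standard multivariate-normal conditioning under the exponential
#' covariance: given the latent field values `omega_obs` at the observed
#' sites, returns the conditional mean `S_no S_oo^-1 omega_obs` and
#' conditional covariance `S_nn - S_no S_oo^-1 S_on` at the new locations.
#' When `sigma2_eps > 0` the observed values are treated as the combined
#' field `omega + eps` (the conditioning covariance gains a `sigma2_eps`
#' diagonal), which marginalizes the spatial/nugget split exactly.
#'
#' @param obs_locations,new_locations Two-column coordinate matrices (km).
#' @param omega_obs Field values at the observed sites.
#' @param sigma2_omega,phi Covariance parameters.
#' @param sigma2_eps Nugget variance carried by the observed field values
#'   (0 for a noise-free field).
#' @param jitter Relative diagonal jitter applied to the observed-site
#'   covariance before factorization.
#' @return List with `mean` (length `n_new`) and `cov` (`n_new x n_new`).
#' @export
conditional_gp_moments <- function(obs_locations, new_locations, omega_obs,
                                   sigma2_omega, phi, sigma2_eps = 0,
                                   jitter = 1e-8) {
  obs_locations <- as.matrix(obs_locations)
  new_locations <- as.matrix(new_locations)
  Doo <- build_distance_matrix(obs_locations, warn_duplicates = FALSE)
  Soo <- exp_cov(Doo, sigma2_omega, phi)
  diag(Soo) <- diag(Soo) + jitter * sigma2_omega + sigma2_eps
  U <- chol(Soo)
  Dno <- sqrt(outer(new_locations[, 1], obs_locations[, 1], "-")^2 +
              outer(new_locations[, 2], obs_locations[, 2], "-")^2)
  Sno <- exp_cov(Dno, sigma2_omega, phi)
  A <- backsolve(U, backsolve(U, t(Sno), transpose = TRUE))  # Soo^-1 Son
  Dnn <- if (nrow(new_locations) == 1) matrix(0, 1, 1)
         else as.matrix(stats::dist(new_locations))
  Snn <- exp_cov(Dnn, sigma2_omega, phi)
  Cv <- unname(Snn - Sno %*% A)
  list(mean = unname(drop(Sno %*% backsolve(U, backsolve(U, omega_obs,
                                                         transpose = TRUE)))),
       cov = (Cv + t(Cv)) / 2)
}

# draws of the spatial field at new locations, conditional on the posterior
# draws of (omega, hypers) at the data sites; block-wise joint simulation
conditional_field_draws <- function(fit, new_locations, draw_idx,
                                    include_nugget = FALSE,
                                    block_size = 256, jitter = 1e-8) {
  new_locations <- as.matrix(new_locations)
  n_new <- nrow(new_locations)
  S <- length(draw_idx)
  out <- matrix(0, S, n_new)
  blocks <- split(seq_len(n_new), ceiling(seq_len(n_new) / block_size))
  for (s in seq_len(S)) {
    th <- fit$draws$theta[draw_idx[s], ]
    s2w <- exp(th[1]); phi <- exp(th[2]); s2e <- exp(th[3])
    if (s2w <= 0) next  # no spatial component in this fit
    u_s <- fit$draws$u[draw_idx[s], ]
    for (b in blocks) {
      # condition omega at new sites on the combined latent field u =
      # omega + eps at the data sites (the split is marginalized exactly)
      mo <- conditional_gp_moments(fit$locations,
                                   new_locations[b, , drop = FALSE],
                                   u_s, s2w, phi, sigma2_eps = s2e,
                                   jitter = jitter)
      Cv <- mo$cov
      diag(Cv) <- diag(Cv) + jitter * s2w
      Ub <- chol(Cv)
      out[s, b] <- mo$mean + drop(crossprod(Ub, stats::rnorm(length(b))))
    }
  }
  if (include_nugget) {
    for (s in seq_len(S)) {
      sde <- exp(fit$draws$theta[draw_idx[s], 3] / 2)
      out[s, ] <- out[s, ] + stats::rnorm(n_new, 0, sde)
    }
  }
  out
}

select_draws <- function(fit, n_draws) {
  S <- nrow(fit$draws$beta)
  if (S < 1) stop("fit contains no posterior draws")
  if (n_draws <= S) {
    unique(round(seq(1, S, length.out = n_draws)))
  } else {
    sample.int(S, n_draws, replace = TRUE)
  }
}

#' Posterior prevalence draws at arbitrary point locations
#'
#' For each retained posterior draw, simulates the spatial effect at the new
#' locations conditional on its value at the data sites (exact multivariate
#' normal conditioning under the exponential covariance) and combines it
#' with the fixed effects; the nugget is excluded by default so that the
#' stable prevalence surface, not cluster-level noise, is predicted.
#'
#' @param fit A `spatial_fit`.
#' @param X_new Design matrix at the new locations (including intercept).
#' @param locations Two-column matrix of new planar-km locations.
#' @param n_draws Number of posterior draws to use.
#' @param seed Integer seed for the conditional simulation.
#' @param include_nugget Add nugget variance to the predictive draws.
#' @return List with `mean`, `sd` (per location) and the `draws` matrix
#'   (`n_draws x n_new`) of prevalence values.
#' @export
predict_at_points <- function(fit, X_new, locations, n_draws = 200,
                              seed = 1, include_nugget = FALSE) {
  stopifnot(inherits(fit, "spatial_fit"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(fit$X))
    stop("X_new must have ", ncol(fit$X), " columns (including intercept)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- select_draws(fit, n_draws)
  omega_new <- conditional_field_draws(fit, locations, idx,
                                       include_nugget = include_nugget,
                                       jitter = fit$config_echo$jitter)
  eta <- tcrossprod(fit$draws$beta[idx, , drop = FALSE], X_new) + omega_new
  p <- stats::plogis(eta)
  list(mean = colMeans(p),
       sd = apply(p, 2, pop_sd),
       draws = p)
}

# SD over posterior draws with divisor n (a single draw has SD 0)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Predict posterior mean and uncertainty prevalence surfaces
#'
#' Evaluates the fitted model on covariate grids (typically 5 km blocks of
#' the native 1 km layers) at every cell centre, by conditional simulation
#' of the spatial effect per posterior draw, and returns the pointwise mean
#' and standard deviation over draws — the prediction and uncertainty
#' surfaces of the atlas.
#'
#' @param fit A `spatial_fit`.
#' @param grids List of `covariate_grid`s, one per covariate the model was
#'   fitted with (same names), all on a common grid.
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed.
#' @param include_nugget Add the nugget variance to cell-level draws.
#' @param block_size Cells per joint conditional-simulation block.
#' @return An object of class `prediction_surface`: list with `mean` and
#'   `sd` (`covariate_grid`s sharing shape and mask) and `n_draws`.
#' @export
predict_surface <- function(fit, grids, n_draws = 200, seed = 1,
                            include_nugget = FALSE, block_size = 256) {
  stopifnot(inherits(fit, "spatial_fit"))
  if (inherits(grids, "covariate_grid")) grids <- list(grids)
  need <- fit$selected_covariates
  nms <- names(grids)
  if (length(need) && !all(need %in% nms))
    stop("grids must be named for covariates: ", paste(need, collapse = ", "))
  ref <- grids[[1]]
  shp <- dim(ref$values)
  for (g in grids)
    if (!all(dim(g$values) == shp) || g$cell != ref$cell ||
        g$xmin != ref$xmin || g$ymin != ref$ymin)
      stop("all grids must share shape and transform")
  centers <- grid_cell_centers(ref)
  covmat <- if (length(need)) {
    do.call(cbind, lapply(need, function(nm) as.vector(t(grids[[nm]]$values))))
  } else NULL
  mask <- if (is.null(covmat)) rep(FALSE, nrow(centers))
          else apply(covmat, 1, anyNA)
  keep <- which(!mask)
  X_new <- cbind(1, if (is.null(covmat)) NULL
                 else covmat[keep, , drop = FALSE])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- select_draws(fit, n_draws)
  omega_new <- conditional_field_draws(fit, centers[keep, , drop = FALSE],
                                       idx, include_nugget = include_nugget,
                                       block_size = block_size,
                                       jitter = fit$config_echo$jitter)
  eta <- tcrossprod(fit$draws$beta[idx, , drop = FALSE], X_new) + omega_new
  p <- stats::plogis(eta)
  mean_v <- rep(NA_real_, nrow(centers)); sd_v <- rep(NA_real_, nrow(centers))
  mean_v[keep] <- colMeans(p)
  sd_v[keep] <- apply(p, 2, pop_sd)
  to_grid <- function(v, nm)
    covariate_grid(matrix(v, shp[1], shp[2], byrow = TRUE),
                   xmin = ref$xmin, ymin = ref$ymin, cell = ref$cell,
                   name = nm)
  structure(list(mean = to_grid(mean_v, "mean"),
                 sd = to_grid(sd_v, "sd"),
                 n_draws = length(idx)),
            class = "prediction_surface")
}

#' @export
print.prediction_surface <- function(x, ...) {
  v <- x$mean$values
  cat(sprintf(
    "prediction_surface: %d x %d cells of %g km, %d draws, mean p in [%.3f, %.3f]\n",
    nrow(v), ncol(v), x$mean$cell, x$n_draws,
    min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}
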