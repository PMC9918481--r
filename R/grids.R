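#' Gridded covariate rasters
#'
#' A `covariate_grid` stores one gridded covariate on a regular planar-km
#' raster. Values are kept as a numeric matrix whose first row is the
#' northernmost row (the usual raster convention); missing cells are `NA` in
#' memory and the nodata sentinel (-9999 by default) on disk. The affine
#' geotransform is the triple (`xmin`, `ymin`, `cell`): the centre of cell
#' `[i, j]` is at `x = xmin + (j - 1/2) cell`, `y = ymax - (i - 1/2) cell`.
#'
#' @param values Numeric matrix (rows north-to-south).
#' @param xmin,ymin South-west corner of the grid in km.
#' @param cell Cell size in km.
#' @param name Optional covariate name.
#' @return An object of class `covariate_grid`.
#' @export
covariate_grid <- function(values, xmin = 0, ymin = 0, cell = 1,
                           name = "cov") {
  stopifnot(is.matrix(values), is.numeric(values), cell > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cell = cell, name = name),
            class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf("covariate_grid '%s': %d x %d cells of %g km, origin (%g, %g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cell, x$xmin, x$ymin))
  invisible(x)
}

grid_ymax <- function(grid) grid$ymin + nrow(grid$values) * grid$cell
grid_xmax <- function(grid) grid$xmin + ncol(grid$values) * grid$cell

#' Cell-centre coordinates of a grid
#'
#' @param grid A `covariate_grid`.
#' @return A two-column matrix (x, y) of all cell centres in row-major order
#'   (matching `as.vector(t(grid$values))`).
#' @export
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$xmin + (seq_len(nc) - 0.5) * grid$cell
  ys <- grid_ymax(grid) - (seq_len(nr) - 0.5) * grid$cell
  cbind(x = rep(xs, times = nr), y = rep(ys, each = nc))
}

#' Simulate smooth gridded covariates over a study domain
#'
#' Generates `k` standardized Gaussian random fields on a regular grid
#' covering the domain extent. Each field is white noise convolved (via FFT,
#' with zero padding so there is no periodic wrap-around) with a
#' squared-exponential kernel of bandwidth `smoothness_km`, then standardized
#' to sample mean 0 and standard deviation 1. This emulates the smooth 1 km
#' geospatial covariate layers used for prevalence mapping.
#'
#' @param domain A `study_domain`.
#' @param k Number of covariate grids.
#' @param cell_km Grid resolution in km (default 1, the native covariate
#'   resolution).
#' @param smoothness_km Kernel standard deviation in km; larger values give
#'   smoother, longer-range fields.
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @return A list of `k` `covariate_grid` objects named `cov_1 ... cov_k`.
#' @export
generate_covariate_grids <- function(domain, k, cell_km = 1,
                                     smoothness_km = 20, seed = 1) {
  stopifnot(inherits(domain, "study_domain"))
  if (k < 1) stop("k must be >= 1")
  if (!is.finite(smoothness_km) || smoothness_km <= 0)
    stop("smoothness_km must be positive")
  nx <- max(1L, as.integer(round((domain$xmax - domain$xmin) / cell_km)))
  ny <- max(1L, as.integer(round((domain$ymax - domain$ymin) / cell_km)))
  pad <- as.integer(ceiling(3 * smoothness_km / cell_km))
  nyp <- ny + 2L * pad; nxp <- nx + 2L * pad
  # separable squared-exponential kernel, centred at element 1 for FFT
  kern1 <- function(n, ell) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * cell_km
    w <- exp(-d^2 / (2 * ell^2))
    w / sum(w)
  }
  ky <- kern1(nyp, smoothness_km)
  kx <- kern1(nxp, smoothness_km)
  fk <- outer(stats::fft(ky), stats::fft(kx))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grids <- vector("list", k)
  for (j in seq_len(k)) {
    z <- matrix(stats::rnorm(nyp * nxp), nyp, nxp)
    sm <- Re(stats::fft(stats::fft(z) * fk, inverse = TRUE)) / (nyp * nxp)
    v <- sm[pad + seq_len(ny), pad + seq_len(nx), drop = FALSE]
    v <- (v - mean(v)) / stats::sd(v)
    grids[[j]] <- covariate_grid(v, xmin = domain$xmin, ymin = domain$ymin,
                                 cell = cell_km, name = paste0("cov_", j))
  }
  names(grids) <- paste0("cov_", seq_len(k))
  grids
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
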