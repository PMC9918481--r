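#' Sample survey cluster locations
#'
#' Draws `n` primary sampling unit (PSU) locations uniformly over the domain
#' extent and assigns each an urban/rural stratum by an independent Bernoulli
#' draw with probability `urban_fraction`. This is a simplified stand-in for
#' a two-stage stratified household-survey design: the spatial model
#' conditions on cluster locations, so downstream fitting is unaffected by
#' the sampling mechanism.
#'
#' @param domain A `study_domain`.
#' @param n Number of clusters (>= 1).
#' @param urban_fraction Probability that a cluster is urban, in \[0, 1\].
#' @param seed Integer seed.
#' @return A data frame with columns `cluster_id`, `x_true`, `y_true`,
#'   `urban` (logical). Reported (displaced) coordinates are added by
#'   [displace_coordinates()].
#' @export
sample_clusters <- function(domain, n, urban_fraction = 0.3, seed = 1) {
  stopifnot(inherits(domain, "study_domain"))
  if (length(domain$districts) == 0) stop("domain has no districts")
  if (n < 1) stop("n must be >= 1")
  if (urban_fraction < 0 || urban_fraction > 1)
    stop("urban_fraction must be in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  data.frame(
    cluster_id = seq_len(n),
    x_true = stats::runif(n, domain$xmin, domain$xmax),
    y_true = stats::runif(n, domain$ymin, domain$ymax),
    urban = stats::runif(n) < urban_fraction)
}

#' Apply DHS-style confidentiality displacement to cluster coordinates
#'
#' Perturbs each true cluster location by a uniform angle and a distance
#' uniform on \[0, cap\], where the cap is 2 km for urban clusters and 5 km
#' for rural clusters, except for a randomly chosen `floor(far_rural_frac *
#' n_rural)` subset of rural clusters whose cap is 10 km. A displaced point
#' that falls outside the domain extent is redrawn (not clipped), preserving
#' the displacement-distance distribution.
#'
#' @param clusters Data frame from [sample_clusters()].
#' @param domain The `study_domain` whose extent bounds reported locations.
#' @param seed Integer seed.
#' @param max_urban_km,max_rural_km,far_rural_km Displacement caps in km.
#' @param far_rural_frac Fraction of rural clusters eligible for the far cap.
#' @return The input with columns `x`, `y` (reported location) and
#'   `far_rural` (logical cap flag) added.
#' @export
displace_coordinates <- function(clusters, domain, seed = 1,
                                 max_urban_km = 2, max_rural_km = 5,
                                 far_rural_km = 10, far_rural_frac = 0.01) {
  stopifnot(all(c("x_true", "y_true", "urban") %in% names(clusters)))
  if (anyNA(clusters$x_true) || anyNA(clusters$y_true))
    stop("true_location must be set for all clusters")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(clusters)
  rural_idx <- which(!clusters$urban)
  n_far <- floor(far_rural_frac * length(rural_idx))
  far <- rep(FALSE, n)
  if (n_far > 0)
    far[sample(rural_idx, n_far)] <- TRUE
  cap <- ifelse(clusters$urban, max_urban_km,
                ifelse(far, far_rural_km, max_rural_km))
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    r <- stats::runif(length(todo), 0, cap[todo])
    a <- stats::runif(length(todo), 0, 2 * pi)
    x[todo] <- clusters$x_true[todo] + r * cos(a)
    y[todo] <- clusters$y_true[todo] + r * sin(a)
    inside <- x[todo] >= domain$xmin & x[todo] <= domain$xmax &
      y[todo] >= domain$ymin & y[todo] <= domain$ymax
    todo <- todo[!inside]
  }
  clusters$x <- x
  clusters$y <- y
  clusters$far_rural <- far
  clusters
}

#' Ground-truth parameters for the generative spatial binomial model
#'
#' Bundles the fixed effects and Gaussian-process hyperparameters used to
#' simulate binomial cluster outcomes. The spatial range is tied to the decay
#' parameter by `range = 3 / phi` (the distance at which the exponential
#' correlation falls to `exp(-3)`); supply exactly one of `phi` or
#' `range_km`.
#'
#' @param beta Coefficient vector including the intercept.
#' @param sigma2_omega Spatial (partial-sill) variance, > 0.
#' @param phi Spatial decay parameter (> 0), or `NULL` if `range_km` given.
#' @param range_km Spatial range in km (> 0), or `NULL` if `phi` given.
#' @param sigma2_eps Nugget (iid) variance, >= 0.
#' @param seed Integer seed used by [simulate_outcomes()].
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(beta, sigma2_omega, phi = NULL, range_km = NULL,
                             sigma2_eps = 0, seed = 1) {
  if (is.null(phi) == is.null(range_km))
    stop("supply exactly one of phi or range_km")
  if (is.null(phi)) phi <- 3 / range_km
  if (sigma2_omega <= 0) stop("sigma2_omega must be > 0")
  if (phi <= 0) stop("phi must be > 0")
  if (sigma2_eps < 0) stop("sigma2_eps must be >= 0")
  structure(list(beta = as.numeric(beta), sigma2_omega = sigma2_omega,
                 phi = phi, range = 3 / phi, sigma2_eps = sigma2_eps,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate binomial outcomes from the spatial generative model
#'
#' Draws the spatial random effect `omega ~ N(0, sigma2_omega *
#' exp(-phi * D))` on the TRUE cluster locations, an independent nugget
#' `eps_i ~ N(0, sigma2_eps)`, sets `p_i = plogis(x_i' beta + omega_i +
#' eps_i)` and draws `y_i ~ Binomial(m, p_i)`. Using true locations for the
#' covariance reflects that confidentiality displacement happens after the
#' outcomes exist.
#'
#' @param clusters Cluster data frame (rows matched to `X`).
#' @param X Design matrix including the intercept column;
#'   `ncol(X) == length(truth$beta)`.
#' @param truth A [simulation_truth()] object (its `seed` drives the draw).
#' @param m_per_cluster Trials per cluster (default 22, the households
#'   sampled per cluster in DHS-style surveys).
#' @return `clusters` with columns `m`, `y_events`, `p_true` and `omega_true`
#'   added.
#' @export
simulate_outcomes <- function(clusters, X, truth, m_per_cluster = 22) {
  stopifnot(inherits(truth, "simulation_truth"))
  X <- as.matrix(X)
  n <- nrow(clusters)
  if (nrow(X) != n) stop("X must have one row per cluster")
  if (ncol(X) != length(truth$beta))
    stop("ncol(X) must equal length(truth$beta)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  eta <- drop(X %*% truth$beta)
  if (truth$sigma2_omega > 0 && n > 1) {
    D <- build_distance_matrix(cbind(clusters$x_true, clusters$y_true),
                               warn_duplicates = FALSE)
    Sigma <- exp_cov(D, truth$sigma2_omega, truth$phi)
    diag(Sigma) <- diag(Sigma) + 1e-8 * truth$sigma2_omega
    U <- tryCatch(chol(Sigma), error = function(e)
      stop("spatial covariance not positive-definite after jitter: ",
           conditionMessage(e)))
    omega <- drop(crossprod(U, stats::rnorm(n)))
  } else {
    omega <- if (truth$sigma2_omega > 0)
      stats::rnorm(n, 0, sqrt(truth$sigma2_omega)) else numeric(n)
  }
  eps <- if (truth$sigma2_eps > 0)
    stats::rnorm(n, 0, sqrt(truth$sigma2_eps)) else numeric(n)
  p <- stats::plogis(eta + omega + eps)
  clusters$m <- as.integer(m_per_cluster)
  clusters$y_events <- stats::rbinom(n, m_per_cluster, p)
  clusters$p_true <- p
  clusters$omega_true <- omega
  clusters
}

#' Attach covariate values at cluster locations
#'
#' Extracts each grid's value at the cluster coordinates (nearest-cell rule)
#' into columns named after the grids.
#'
#' @param clusters Cluster data frame.
#' @param grids List of `covariate_grid`s.
#' @param use `"reported"` (columns `x`, `y`; the default, matching common
#'   practice with displaced survey coordinates) or `"true"`.
#' @return `clusters` with one numeric column per grid appended.
#' @export
attach_covariates <- function(clusters, grids, use = c("reported", "true")) {
  use <- match.arg(use)
  pts <- if (use == "reported") cbind(clusters$x, clusters$y)
         else cbind(clusters$x_true, clusters$y_true)
  vals <- extract_at_points(grids, pts)
  for (nm in colnames(vals)) clusters[[nm]] <- vals[, nm]
  clusters
}
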