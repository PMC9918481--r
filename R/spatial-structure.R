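#' Euclidean distance matrix between cluster locations
#'
#' @param locations Two-column matrix of planar-km coordinates.
#' @param warn_duplicates Warn when two locations coincide (zero off-diagonal
#'   distance); duplicates are allowed.
#' @return The symmetric `n x n` distance matrix in km with zero diagonal.
#' @export
build_distance_matrix <- function(locations, warn_duplicates = TRUE) {
  locations <- as.matrix(locations)
  if (nrow(locations) < 2) stop("need at least 2 locations")
  D <- as.matrix(stats::dist(locations))
  dimnames(D) <- NULL
  if (warn_duplicates && any(D[upper.tri(D)] == 0))
    warning("duplicated locations: distance matrix has zero off-diagonal entries")
  D
}

#' Exponential covariance function
#'
#' `Sigma = sigma2_omega * exp(-phi * D)` elementwise. The spatial range is
#' `3 / phi`: at that distance the correlation equals `exp(-3)` (~0.0498).
#'
#' @param D Distance matrix (km) or numeric distances.
#' @param sigma2_omega Spatial variance (> 0).
#' @param phi Decay parameter (> 0).
#' @return Covariance matrix (or vector) with the shape of `D`.
#' @export
exp_cov <- function(D, sigma2_omega, phi) {
  if (sigma2_omega <= 0) stop("sigma2_omega must be > 0")
  if (phi <= 0) stop("phi must be > 0")
  sigma2_omega * exp(-phi * D)
}

#' Prior specification for the spatial binomial model
#'
#' Defaults follow the atlas model: independent `N(0, 1000)` priors on each
#' regression coefficient; a `Gamma(2, 1)` prior on the precision of the iid
#' (nugget) random effect; a penalized-complexity (PC) prior on the spatial
#' range with `P(range < r0) = 0.01`, where `r0` defaults to 5% of the
#' east-west extent of the domain; and a PC (exponential) prior on the
#' partial sill `sigma_omega` with `P(sigma_omega > 3) = 0.01`.
#'
#' Two printed-form switches are provided. `sigma_prior_direction =
#' "as_printed"` flips the sill prior to `P(sigma_omega < 3) = 0.01`
#' (placing 99% of mass above 3, an implausibly diffuse choice on the logit
#' scale, hence not the default). `iid_prior = "as_printed"` places the
#' `Gamma(2, 1)` density on the nugget variance instead of the precision.
#'
#' @param domain A `study_domain`, used to compute the default `r0`.
#' @param r0 Range-prior threshold in km; overrides the 5%-of-extent default.
#' @param alpha_range Tail probability for the range PC prior.
#' @param sigma_u,alpha_sigma PC-prior threshold and tail probability for the
#'   partial sill.
#' @param beta_sd2 Prior variance of each regression coefficient.
#' @param iid_gamma_shape,iid_gamma_rate Gamma prior parameters for the iid
#'   effect.
#' @param sigma_prior_direction `"standard"` (`P(sigma > u) = alpha`) or
#'   `"as_printed"` (`P(sigma < u) = alpha`).
#' @param iid_prior `"precision"` or `"as_printed"` (density on the
#'   variance).
#' @return An object of class `prior_spec`.
#' @export
default_priors <- function(domain = NULL, r0 = NULL, alpha_range = 0.01,
                           sigma_u = 3, alpha_sigma = 0.01, beta_sd2 = 1000,
                           iid_gamma_shape = 2, iid_gamma_rate = 1,
                           sigma_prior_direction = c("standard", "as_printed"),
                           iid_prior = c("precision", "as_printed")) {
  sigma_prior_direction <- match.arg(sigma_prior_direction)
  iid_prior <- match.arg(iid_prior)
  if (is.null(r0)) {
    if (is.null(domain)) stop("supply a domain or an explicit r0")
    width <- domain$xmax - domain$xmin
    if (width <= 0) stop("domain east-west extent must be positive")
    r0 <- 0.05 * width
  }
  if (r0 <= 0 || alpha_range <= 0 || alpha_range >= 1 || sigma_u <= 0 ||
      alpha_sigma <= 0 || alpha_sigma >= 1 || beta_sd2 <= 0 ||
      iid_gamma_shape <= 0 || iid_gamma_rate <= 0)
    stop("invalid prior parameters")
  structure(list(beta_sd2 = beta_sd2, iid_gamma_shape = iid_gamma_shape,
                 iid_gamma_rate = iid_gamma_rate, r0 = r0,
                 alpha_range = alpha_range, sigma_u = sigma_u,
                 alpha_sigma = alpha_sigma,
                 sigma_prior_direction = sigma_prior_direction,
                 iid_prior = iid_prior),
            class = "prior_spec")
}

# --- log prior densities on the sampler's log-scale hyperparameters -------
# theta = (log sigma2_omega, log phi, log sigma2_eps); each function returns
# the log density INCLUDING the Jacobian of the log transform.

# PC prior for the range of an exponential-covariance field in d = 2:
# pi(r) = lambda r^-2 exp(-lambda / r), lambda = -r0 * log(alpha), so that
# P(range < r0) = alpha. Parametrized via log phi with range = 3 / phi.
log_prior_logphi <- function(log_phi, priors) {
  r <- 3 / exp(log_phi)
  lambda <- -priors$r0 * log(priors$alpha_range)
  log(lambda) - log(r) - lambda / r
}

# PC (exponential) prior on sigma_omega, via log sigma2_omega.
log_prior_logsigma2_omega <- function(log_s2, priors) {
  sigma <- exp(log_s2 / 2)
  if (priors$sigma_prior_direction == "standard") {
    lambda <- -log(priors$alpha_sigma) / priors$sigma_u
  } else {
    lambda <- -log1p(-priors$alpha_sigma) / priors$sigma_u
  }
  log(lambda) - lambda * sigma + log(sigma / 2)
}

# Gamma(2,1) on the iid precision (default) or on the variance (as printed),
# via log sigma2_eps.
log_prior_logsigma2_eps <- function(log_s2, priors) {
  a <- priors$iid_gamma_shape; b <- priors$iid_gamma_rate
  if (priors$iid_prior == "precision") {
    tau <- exp(-log_s2)
    a * log(tau) - b * tau   # (a-1) log tau - b tau + log|d tau/d log s2|
  } else {
    v <- exp(log_s2)
    a * log(v) - b * v
  }
}

log_prior_beta <- function(beta, priors) {
  sum(stats::dnorm(beta, 0, sqrt(priors$beta_sd2), log = TRUE))
}
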