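# Small synthetic studies built in code for the tests.

# Complete small study: domain, smooth covariate grids, displaced clusters
# with covariates attached and binomial outcomes simulated from the
# spatial generative model.
make_test_study <- function(n = 120, k_cov = 2, beta = c(-1, 0.5, -0.3),
                            sigma2_omega = 0.5, range_km = 40,
                            sigma2_eps = 0, m = 22, seed = 1,
                            n_x = 4, n_y = 4, district_km = 50,
                            grid_cell_km = 2, smoothness_km = 25) {
  stopifnot(length(beta) == k_cov + 1)
  dom <- generate_domain(n_x, n_y, district_km)
  grids <- generate_covariate_grids(dom, k_cov, cell_km = grid_cell_km,
                                    smoothness_km = smoothness_km,
                                    seed = seed + 1000L)
  cl <- sample_clusters(dom, n, 0.3, seed = seed + 2000L)
  cl <- displace_coordinates(cl, dom, seed = seed + 3000L)
  cl <- attach_covariates(cl, grids)
  truth <- simulation_truth(beta, sigma2_omega = sigma2_omega,
                            range_km = range_km, sigma2_eps = sigma2_eps,
                            seed = seed + 4000L)
  X <- cbind(1, as.matrix(cl[, names(grids), drop = FALSE]))
  cl <- simulate_outcomes(cl, X, truth, m_per_cluster = m)
  list(domain = dom, grids = grids, clusters = cl, truth = truth,
       cov_names = names(grids))
}

# Independent binomial design for the covariate-selection tests:
# orthogonalized covariate columns and outcomes from a plain logistic model
# (no spatial effect), so selection behaviour is driven by the effects.
make_selection_data <- function(n = 500, effects = c(1, 0.8, 0, 0, 0),
                                intercept = -1, m = 22, seed = 1) {
  set.seed(seed)
  p <- length(effects)
  Z <- matrix(rnorm(n * p), n, p)
  X <- qr.Q(qr(Z))[, seq_len(p), drop = FALSE] * sqrt(n)  # orthogonal columns
  colnames(X) <- paste0("cov_", seq_len(p))
  eta <- intercept + drop(X %*% effects)
  y <- rbinom(n, m, plogis(eta))
  list(X = X, y = y, m = rep(m, n))
}

# quick short-chain inference config for unit tests
fast_config <- function(seed = 1, n_iter = 800, burn_in = 300, thin = 2, ...)
  inference_config(seed = seed, n_iter = n_iter, burn_in = burn_in,
                   thin = thin, ...)
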