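#' Serialize a spatial fit to a directory of text files
#'
#' Writes `beta_summary.csv`, `hyper_summary.csv`, `latent_p.csv`,
#' `diagnostics.json`, the posterior draw matrices (`draws_beta.csv`,
#' `draws_theta.csv`, `draws_omega.csv`) and the data-site locations, so a
#' fit can be reloaded for prediction.
#'
#' @param fit A `spatial_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "spatial_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(fit$beta_summary, "beta_summary.csv")
  w(fit$hyper_summary, "hyper_summary.csv")
  w(fit$latent_p, "latent_p.csv")
  bd <- as.data.frame(fit$draws$beta)
  names(bd) <- fit$beta_summary$parameter
  w(bd, "draws_beta.csv")
  td <- as.data.frame(fit$draws$theta)
  names(td) <- c("log_sigma2_omega", "log_phi", "log_sigma2_eps")
  w(td, "draws_theta.csv")
  w(as.data.frame(fit$draws$u), "draws_u.csv")
  w(data.frame(x = fit$locations[, 1], y = fit$locations[, 2]),
    "locations.csv")
  jsonlite::write_json(
    c(fit$diagnostics,
      list(selected_covariates = fit$selected_covariates,
           use_locations = fit$config_echo$use_locations,
           jitter = fit$config_echo$jitter,
           seed = fit$config_echo$seed)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_fit
#' @return `load_fit()` returns a `spatial_fit` sufficient for prediction
#'   (summaries, draws, locations; no raw data).
#' @export
load_fit <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  diag_js <- jsonlite::read_json(file.path(dir, "diagnostics.json"),
                                 simplifyVector = TRUE)
  beta <- as.matrix(rd("draws_beta.csv"))
  fit <- list(
    beta_summary = rd("beta_summary.csv"),
    hyper_summary = rd("hyper_summary.csv"),
    latent_p = rd("latent_p.csv"),
    draws = list(beta = beta,
                 theta = as.matrix(rd("draws_theta.csv")),
                 u = as.matrix(rd("draws_u.csv"))),
    diagnostics = diag_js,
    config_echo = list(use_locations = diag_js$use_locations,
                       jitter = diag_js$jitter, seed = diag_js$seed,
                       fix = list()),
    locations = as.matrix(rd("locations.csv")),
    selected_covariates = diag_js$selected_covariates,
    X = matrix(NA_real_, 0, ncol(beta)))
  class(fit) <- "spatial_fit"
  fit
}

#' Run the full synthetic atlas study end to end
#'
#' Generates a synthetic study (districts, displaced clusters, covariate
#' grids, binomial outcomes from the spatial generative model), selects
#' covariates, fits the spatial model, predicts 5 km mean and uncertainty
#' surfaces, cross-validates, and produces district-level tables (zonal
#' means of the surface and survey-based Wilson estimates). All outputs are
#' plain text and byte-reproducible given the seed.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param out Output directory, or `NULL` to skip writing files.
#' @param n_x,n_y,district_km Domain layout (default 4 x 4 districts of 50
#'   km).
#' @param n_clusters Number of survey clusters.
#' @param n_covariates Number of simulated covariate layers.
#' @param urban_fraction Urban cluster share.
#' @param smoothness_km Covariate field smoothness.
#' @param truth A [simulation_truth()]; default uses intercept -1, effects
#'   `(0.5, -0.3, 0, ...)`, spatial variance 0.5, range 40 km, nugget 0.05.
#' @param m_per_cluster Trials per cluster.
#' @param config An [inference_config()] (its seed is overridden by `seed`).
#' @param k_cv Cross-validation folds.
#' @param n_draws Posterior draws for prediction surfaces.
#' @param aggregate_factor Covariate aggregation factor (native 1 km cells
#'   to the 5 km modelling resolution).
#' @return List with `domain`, `clusters`, `selection`, `fit`, `surface`,
#'   `cv`, `zonal`, `district_table`, and the output paths written.
#' @export
run_atlas <- function(seed = 1, out = NULL, n_x = 4, n_y = 4,
                      district_km = 50, n_clusters = 250, n_covariates = 4,
                      urban_fraction = 0.3, smoothness_km = 30,
                      truth = NULL, m_per_cluster = 22,
                      config = inference_config(), k_cv = 5, n_draws = 100,
                      aggregate_factor = 5) {
  domain <- generate_domain(n_x, n_y, district_km)
  grids1 <- generate_covariate_grids(domain, n_covariates, cell_km = 1,
                                     smoothness_km = smoothness_km,
                                     seed = seed + 1L)
  clusters <- sample_clusters(domain, n_clusters, urban_fraction,
                              seed = seed + 2L)
  clusters <- displace_coordinates(clusters, domain, seed = seed + 3L)
  clusters <- attach_covariates(clusters, grids1, use = "reported")
  cov_names <- names(grids1)
  if (is.null(truth)) {
    effects <- rep(0, n_covariates)
    effects[seq_len(min(2, n_covariates))] <-
      c(0.5, -0.3)[seq_len(min(2, n_covariates))]
    truth <- simulation_truth(beta = c(-1, effects), sigma2_omega = 0.5,
                              range_km = 40, sigma2_eps = 0.05,
                              seed = seed + 4L)
  }
  X_gen <- cbind(1, as.matrix(clusters[, cov_names, drop = FALSE]))
  clusters <- simulate_outcomes(clusters, X_gen, truth, m_per_cluster)

  X <- as.matrix(clusters[, cov_names, drop = FALSE])
  selection <- select_covariates(X, clusters$y_events, clusters$m)
  priors <- default_priors(domain)
  config$seed <- as.integer(seed + 5L)
  fit <- fit_spatial_binomial(clusters, selection$final_names, priors,
                              config)
  grids5 <- lapply(grids1, aggregate_grid, factor = aggregate_factor)
  surface <- predict_surface(fit, grids5, n_draws = n_draws,
                             seed = seed + 6L)
  cv <- cross_validate(clusters, selection$final_names, priors, k = k_cv,
                       config = config, n_draws = max(50, n_draws %/% 2))
  zonal <- zonal_mean(surface, domain)

  # district survey-based proportions with Wilson intervals
  dists <- vapply(domain$districts, function(d)
    sum(points_in_polygon(cbind(clusters$x, clusters$y), d$ring) *
          clusters$y_events), 0)
  trials <- vapply(domain$districts, function(d)
    sum(points_in_polygon(cbind(clusters$x, clusters$y), d$ring) *
          clusters$m), 0)
  ids <- vapply(domain$districts, `[[`, 0L, "id")
  have <- trials > 0
  district_table <- district_estimates(
    data.frame(district_id = ids[have], events = dists[have],
               exposure = trials[have], family = "proportion"))

  paths <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_districts(domain, file.path(out, "districts.geojson"))
    write_clusters(clusters, file.path(out, "clusters.csv"))
    utils::write.csv(data.frame(covariate = selection$final_names),
                     file.path(out, "selected_covariates.csv"),
                     row.names = FALSE)
    save_fit(fit, file.path(out, "fit"))
    write_raster(surface$mean, file.path(out, "prevalence_mean.asc"))
    write_raster(surface$sd, file.path(out, "prevalence_sd.asc"))
    jsonlite::write_json(list(k = cv$k, per_fold = cv$per_fold,
                              pooled = cv$pooled, seed = cv$seed),
                         file.path(out, "cv.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(zonal, file.path(out, "zonal_means.csv"),
                     row.names = FALSE)
    utils::write.csv(district_table, file.path(out, "district_estimates.csv"),
                     row.names = FALSE)
    paths <- list.files(out, recursive = TRUE, full.names = TRUE)
  }
  list(domain = domain, clusters = clusters, selection = selection,
       fit = fit, surface = surface, cv = cv, zonal = zonal,
       district_table = district_table, truth = truth, paths = paths)
}
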