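test_that("aggregate_grid matches the nested-loop block-mean oracle", {
  g <- covariate_grid(matrix(c(1, 3, 2, 4), 2, 2), cell = 1)
  expect_identical(aggregate_grid(g, 1), g)
  expect_equal(aggregate_grid(g, 2)$values, matrix(2.5, 1, 1))

  set.seed(60)
  v <- matrix(rnorm(100), 10, 10)
  v[sample(100, 12)] <- NA
  g10 <- covariate_grid(v, xmin = 5, ymin = -5, cell = 2)
  a <- aggregate_grid(g10, 5)
  expect_equal(dim(a$values), c(2, 2))
  expect_equal(a$cell, 10)
  for (bi in 1:2) for (bj in 1:2) {
    blk <- v[(bi - 1) * 5 + 1:5, (bj - 1) * 5 + 1:5]
    expect_equal(a$values[bi, bj], mean(blk, na.rm = TRUE),
                 tolerance = 1e-12)
  }

  # all-missing block propagates missingness
  v2 <- matrix(1, 4, 4); v2[1:2, 1:2] <- NA
  a2 <- aggregate_grid(covariate_grid(v2, cell = 1), 2)
  expect_true(is.na(a2$values[1, 1]))
  expect_equal(a2$values[2, 2], 1)

  # partial edge blocks average over the cells present
  v3 <- matrix(seq_len(9), 3, 3)
  a3 <- aggregate_grid(covariate_grid(v3, cell = 1), 2)
  expect_equal(dim(a3$values), c(2, 2))
  expect_equal(a3$values[2, 2], v3[3, 3])
})

test_that("extract_at_points uses the half-open nearest-cell rule", {
  # 2 x 2 grid on [0,2]^2, cell centres at 0.5/1.5
  g <- covariate_grid(matrix(c(11, 21, 12, 22), 2, 2), cell = 1)
  # north-west cell is values[1, 1]
  expect_equal(extract_at_points(g, rbind(c(0.5, 1.5)))[1], 11)
  expect_equal(extract_at_points(g, rbind(c(1.5, 1.5)))[1], 12)
  expect_equal(extract_at_points(g, rbind(c(0.5, 0.5)))[1], 21)
  # vertical boundary x = 1 belongs to the eastern cell
  expect_equal(extract_at_points(g, rbind(c(1, 1.5)))[1], 12)
  # horizontal boundary y = 1 belongs to the southern cell
  expect_equal(extract_at_points(g, rbind(c(0.5, 1)))[1], 21)

  expect_error(extract_at_points(g, rbind(c(2.5, 0.5))), "outside")

  # index-arithmetic oracle on random points
  set.seed(61)
  vv <- matrix(rnorm(15 * 12), 15, 12)
  gg <- covariate_grid(vv, xmin = -3, ymin = 7, cell = 0.5)
  pts <- cbind(runif(100, -3, -3 + 12 * 0.5 - 1e-9),
               runif(100, 7, 7 + 15 * 0.5 - 1e-9))
  got <- extract_at_points(gg, pts)
  for (k in 1:100) {
    j <- floor((pts[k, 1] + 3) / 0.5) + 1
    i <- floor((7 + 15 * 0.5 - pts[k, 2]) / 0.5) + 1
    expect_identical(unname(got[k, 1]), vv[i, j])
  }
})

test_that("conditional GP moments match closed-form MVN conditioning", {
  set.seed(62)
  obs <- matrix(runif(10, 0, 100), 5, 2)
  new <- matrix(runif(6, 0, 100), 3, 2)
  omega <- rnorm(5)
  s2 <- 0.8; phi <- 0.04
  mo <- conditional_gp_moments(obs, new, omega, s2, phi, jitter = 0)
  # naive oracle with explicit solve()
  all_pts <- rbind(obs, new)
  S <- s2 * exp(-phi * as.matrix(dist(all_pts)))
  Soo <- S[1:5, 1:5]; Sno <- S[6:8, 1:5]; Snn <- S[6:8, 6:8]
  mu_o <- Sno %*% solve(Soo, omega)
  cv_o <- Snn - Sno %*% solve(Soo, t(Sno))
  expect_equal(mo$mean, unname(drop(mu_o)), tolerance = 1e-8)
  expect_equal(mo$cov, unname((cv_o + t(cv_o)) / 2), tolerance = 1e-8)
  # at an observed site the field interpolates exactly
  mo2 <- conditional_gp_moments(obs, obs[2, , drop = FALSE], omega, s2, phi,
                                jitter = 0)
  expect_equal(mo2$mean, omega[2], tolerance = 1e-6)
  expect_lt(mo2$cov[1, 1], 1e-6)
})

test_that("predict_surface reduces to the covariate-only limit without random effects", {
  st <- make_test_study(n = 120, sigma2_omega = 1e-6, sigma2_eps = 0,
                        seed = 63, grid_cell_km = 10)
  fit <- fit_spatial_binomial(st$clusters, st$cov_names,
                              default_priors(st$domain),
                              fast_config(seed = 64, n_iter = 1500,
                                          burn_in = 500,
                                          fix = list(sigma2_omega = 0,
                                                     sigma2_eps = 0)))
  grids20 <- lapply(st$grids, aggregate_grid, factor = 2)
  sf <- predict_surface(fit, grids20, n_draws = 200, seed = 65)
  bmean <- fit$beta_summary$mean
  Xg <- cbind(1, as.vector(t(grids20$cov_1$values)),
              as.vector(t(grids20$cov_2$values)))
  expected <- plogis(drop(Xg %*% bmean))
  got <- as.vector(t(sf$mean$values))
  expect_lt(max(abs(got - expected)), 0.03)
  expect_true(all(got > 0 & got < 1))
  # a single draw has zero spread by construction
  sf1 <- predict_surface(fit, grids20, n_draws = 1, seed = 66)
  expect_true(all(sf1$sd$values == 0))
})

test_that("prediction interpolates the data where the signal is strong", {
  # one cluster with huge m and y/m = 0.8 dominates its neighbourhood
  st <- make_test_study(n = 60, seed = 67)
  cl <- st$clusters
  cl$m <- rep(10000L, nrow(cl))
  cl$y_events <- as.integer(round(cl$m * 0.8))
  fit <- fit_spatial_binomial(cl, character(0), default_priors(st$domain),
                              fast_config(seed = 68, n_iter = 1200,
                                          burn_in = 400))
  pr <- predict_at_points(fit, matrix(1, 3, 1),
                          cbind(cl$x[1:3], cl$y[1:3]),
                          n_draws = 150, seed = 69)
  expect_true(all(abs(pr$mean - 0.8) < 0.05))
})

test_that("masked cells stay masked through prediction and the SD shrinks with draws", {
  st <- make_test_study(n = 80, seed = 70, grid_cell_km = 10)
  grids20 <- lapply(st$grids, aggregate_grid, factor = 2)
  grids20$cov_1$values[2, 3] <- NA
  fit <- fit_spatial_binomial(st$clusters, st$cov_names,
                              default_priors(st$domain),
                              fast_config(seed = 71))
  sf <- predict_surface(fit, grids20, n_draws = 40, seed = 72)
  expect_true(is.na(sf$mean$values[2, 3]))
  expect_true(is.na(sf$sd$values[2, 3]))
  expect_true(all(!is.na(sf$mean$values[-((3 - 1) * 10 + 2)])))
  expect_true(all(sf$sd$values >= 0, na.rm = TRUE))
})
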