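test_that("pearson_matrix matches a brute-force covariance oracle", {
  set.seed(10)
  X <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  R <- pearson_matrix(X)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R, t(R))
  # direct-sums oracle
  for (i in 1:3) for (j in 1:3) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    expect_equal(R[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)))
  }

  Xd <- cbind(X, d = X[, 1])
  expect_equal(pearson_matrix(Xd)["a", "d"], 1)
  # orthogonalized centred columns have zero correlation
  M <- scale(matrix(rnorm(200), 50, 4), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  Ro <- pearson_matrix(Q)
  expect_true(all(abs(Ro[upper.tri(Ro)]) < 1e-12))

  expect_error(pearson_matrix(cbind(a = rnorm(10), b = rep(2, 10))), "b")
})

test_that("flag_collinear_pairs flags |r| above the threshold once per pair", {
  expect_identical(nrow(flag_collinear_pairs(diag(3))), 0L)
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.85
  fl <- flag_collinear_pairs(R)
  expect_equal(fl, data.frame(i = 1L, j = 2L, r = 0.85))
  # four mutually correlated columns -> choose(4, 2) = 6 pairs
  R4 <- matrix(0.9, 4, 4); diag(R4) <- 1
  expect_identical(nrow(flag_collinear_pairs(R4)), 6L)
  # strong negative correlation is flagged too
  Rn <- diag(2); Rn[1, 2] <- Rn[2, 1] <- -0.9
  expect_identical(nrow(flag_collinear_pairs(Rn)), 1L)
})

test_that("fit_binomial_glm reproduces closed forms and flags separation", {
  # intercept-only, y/m = 0.25 everywhere
  f0 <- fit_binomial_glm(NULL, y = rep(5, 20), m = rep(20, 20))
  expect_equal(unname(f0$coefficients), qlogis(0.25), tolerance = 1e-8)
  expect_true(f0$converged)

  # one binary covariate: slope = logit(p1) - logit(p0)
  x <- rep(c(0, 1), each = 25)
  y <- ifelse(x == 0, 4, 12)  # prevalences 0.2 and 0.6 at m = 20
  f1 <- fit_binomial_glm(cbind(g = x), y = y, m = rep(20, 50))
  expect_equal(unname(f1$coefficients),
               c(qlogis(0.2), qlogis(0.6) - qlogis(0.2)), tolerance = 1e-8)

  # y = m everywhere: separation flagged, never silent
  expect_warning(fs <- fit_binomial_glm(cbind(x = rnorm(30)),
                                        y = rep(10, 30), m = rep(10, 30)))
  expect_false(fs$converged)
})

test_that("bic uses the cluster count and matches stats::BIC", {
  fake <- structure(list(log_likelihood = -100, n_params = 3, n_obs = 100,
                         converged = TRUE), class = "glm_fit")
  expect_equal(bic(fake), 200 + 3 * log(100))
  expect_equal(bic(fake), 213.8155106, tolerance = 1e-7)

  # ln(1) = 0: penalty vanishes at n = 1
  fake1 <- structure(list(log_likelihood = -2, n_params = 2, n_obs = 1,
                          converged = TRUE), class = "glm_fit")
  expect_equal(bic(fake1), 4)

  # monotone penalty at equal likelihood
  fake2 <- structure(list(log_likelihood = -100, n_params = 2, n_obs = 100,
                          converged = TRUE), class = "glm_fit")
  expect_lt(bic(fake2), bic(fake))

  # oracle: agrees with stats::BIC on a real fit (same n convention)
  sd <- make_selection_data(n = 200, effects = c(0.5, 0), seed = 3)
  f <- fit_binomial_glm(sd$X, sd$y, sd$m)
  expect_equal(bic(f), BIC(f$glm), tolerance = 1e-8)

  fake_nc <- structure(list(converged = FALSE), class = "glm_fit")
  expect_error(bic(fake_nc))
})

test_that("resolve_collinear retains the lower-BIC member of each pair", {
  sd <- make_selection_data(n = 300, effects = c(1, 0), seed = 4)
  X <- sd$X
  expect_identical(resolve_collinear(X, sd$y, sd$m, NULL), 1:2)

  # duplicated column: exactly one of the pair survives (tie -> lower index)
  Xd <- cbind(X, dup = X[, 1])
  fl <- flag_collinear_pairs(pearson_matrix(Xd))
  expect_warning(keep <- resolve_collinear(Xd, sd$y, sd$m, fl), "tie")
  expect_true(xor(1 %in% keep, 3 %in% keep))

  # true predictor vs noisy copy: the true one wins almost always
  wins <- 0
  for (r in 1:200) {
    set.seed(800 + r)
    a <- rnorm(150)
    b <- a + rnorm(150, 0, 0.25)
    eta <- -0.5 + a
    y <- rbinom(150, 15, plogis(eta))
    Xp <- cbind(a = a, b = b)
    flp <- flag_collinear_pairs(pearson_matrix(Xp))
    expect_identical(nrow(flp), 1L)
    keep <- resolve_collinear(Xp, y, rep(15, 150), flp)
    if (identical(keep, 1L)) wins <- wins + 1
  }
  expect_gte(wins / 200, 0.95)
})

test_that("vif_filter matches an explicit least-squares oracle", {
  set.seed(12)
  n <- 100
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  # near-orthogonal noise columns: all VIFs near 1, nothing removed
  expect_identical(vif_filter(X), 1:3)
  vifs <- vif_values(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(vifs[j]), 1 / (1 - r2), tolerance = 1e-10)
  }

  # exact linear dependence: one of the trio goes first
  Xs <- cbind(X[, 1:2], s = X[, 1] + X[, 2])
  expect_length(vif_filter(Xs), 2)

  # strongly inflated design gets trimmed below the threshold
  Xc <- cbind(a = rnorm(n))
  Xc <- cbind(Xc, b = Xc[, 1] + rnorm(n, 0, 0.2), c = rnorm(n))
  kept <- vif_filter(Xc, threshold = 4)
  expect_true(all(vif_values(cbind(Xc[, kept], rnorm(n))) [seq_along(kept)] < 4 |
                  length(kept) < 2))
  # idempotent
  expect_identical(vif_filter(Xc[, kept, drop = FALSE]),
                   seq_along(kept))
})

test_that("backward_select is greedy steepest-descent with decreasing BIC", {
  # single useless covariate: removed, final set empty
  sd0 <- make_selection_data(n = 400, effects = 0, seed = 5)
  tr0 <- backward_select(sd0$X, sd0$y, sd0$m)
  expect_length(tr0$final_set, 0)
  expect_identical(nrow(tr0$stepwise_path), 1L)

  # strong covariate among nulls is retained, path strictly decreasing
  sd1 <- make_selection_data(n = 500, effects = c(1, 0, 0, 0, 0), seed = 6)
  tr1 <- backward_select(sd1$X, sd1$y, sd1$m)
  expect_true(1 %in% tr1$final_set)
  if (nrow(tr1$stepwise_path) > 0) {
    expect_true(all(tr1$stepwise_path$bic_after <
                    tr1$stepwise_path$bic_before))
  }
  # local optimality: no further single removal lowers the BIC
  fit_set <- function(set) bic(fit_binomial_glm(
    if (length(set)) sd1$X[, set, drop = FALSE] else NULL, sd1$y, sd1$m))
  for (j in seq_along(tr1$final_set))
    expect_gte(fit_set(tr1$final_set[-j]), tr1$final_bic)
})

test_that("backward selection keeps a strong covariate with high power", {
  hits <- 0
  for (r in 1:50) {
    sd <- make_selection_data(n = 500, effects = c(1, 0, 0, 0, 0),
                              seed = 3000 + r)
    tr <- backward_select(sd$X, sd$y, sd$m)
    if (1 %in% tr$final_set) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("the full selection pipeline is deterministic and idempotent", {
  sd <- make_selection_data(n = 300, effects = c(0.8, 0.5, 0), seed = 7)
  X <- cbind(sd$X, extra = sd$X[, 1] + rnorm(300, 0, 0.1))
  s1 <- suppressWarnings(select_covariates(X, sd$y, sd$m))
  s2 <- suppressWarnings(select_covariates(X, sd$y, sd$m))
  expect_identical(s1, s2)
  expect_length(intersect(s1$final_set,
                          c(s1$dropped_by_bic, s1$dropped_by_vif)), 0)
  # re-screening the selected columns changes nothing
  Xf <- X[, s1$final_set, drop = FALSE]
  R <- pearson_matrix(Xf)
  expect_identical(nrow(flag_collinear_pairs(R)), 0L)
  if (ncol(Xf) >= 2) expect_identical(vif_filter(Xf), seq_len(ncol(Xf)))
})
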