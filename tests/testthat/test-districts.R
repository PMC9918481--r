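test_that("wilson_ci closed forms and symmetry", {
  z <- qnorm(0.975)
  ci0 <- wilson_ci(0, 22)
  expect_identical(unname(ci0[1]), 0)
  expect_equal(unname(ci0[2]), z^2 / (22 + z^2), tolerance = 1e-10)
  expect_equal(unname(ci0[2]), 0.1486549, tolerance = 1e-6)

  ci_full <- wilson_ci(22, 22)
  expect_identical(unname(ci_full[2]), 1)
  expect_equal(unname(ci_full[1]), 1 - z^2 / (22 + z^2), tolerance = 1e-10)

  ci_half <- wilson_ci(11, 22)
  expect_equal(unname(ci_half[1] + ci_half[2]), 1, tolerance = 1e-12)

  expect_error(wilson_ci(5, 0))
  expect_error(wilson_ci(-1, 10))
})

test_that("wilson coverage is near nominal by exact binomial enumeration", {
  cov_exact <- function(p, m = 22) {
    covers <- vapply(0:m, function(y) {
      ci <- wilson_ci(y, m)
      ci[1] <= p && p <= ci[2]
    }, TRUE)
    sum(dbinom(0:m, m, p) * covers)
  }
  for (p in c(0.05, 0.3, 0.5)) expect_gte(cov_exact(p), 0.93)
  # at moderate p the interval is close to nominal from above too
  for (p in c(0.3, 0.5)) expect_lte(cov_exact(p), 0.97)
  # at p = 0.05 with m = 22 the discrete Wilson interval is conservative:
  # exact coverage is ~0.978, a property of the interval, not a defect
  expect_lte(cov_exact(0.05), 0.985)
})

test_that("byar_ci approaches the exact Poisson limits as counts grow", {
  ci100 <- byar_ci(100, 1)
  ex100 <- exact_poisson_ci(100, 1)
  expect_lt(max(abs(ci100 - ex100) / ex100), 0.005)
  ci20 <- byar_ci(20, 1)
  ex20 <- exact_poisson_ci(20, 1)
  expect_lt(max(abs(ci20 - ex20) / ex20), 0.02)

  ci6 <- byar_ci(6, 1)
  expect_lt(ci6[1], 6); expect_gt(ci6[2], 6)
  # rate scaling: denominator x10 divides both endpoints by 10
  expect_equal(unname(byar_ci(30, 10)), unname(byar_ci(30, 1)) / 10)
  expect_error(byar_ci(10, 0))
})

test_that("exact Poisson limits satisfy their defining tail equations", {
  for (count in c(1, 3, 7, 40)) {
    ci <- exact_poisson_ci(count, 1)
    # upper tail at the lower limit: P(X >= count | lo) = 0.025
    lo_tail <- 1 - ppois(count - 1, ci[1])
    # lower tail at the upper limit: P(X <= count | hi) = 0.025
    hi_tail <- ppois(count, ci[2])
    expect_equal(unname(lo_tail), 0.025, tolerance = 1e-8)
    expect_equal(unname(hi_tail), 0.025, tolerance = 1e-8)
  }
  expect_identical(unname(exact_poisson_ci(0, 1)[1]), 0)

  # independent bisection oracle on the summed Poisson tails
  count <- 3
  f_lo <- function(l) sum(dpois(count:200, l)) - 0.025
  f_hi <- function(l) sum(dpois(0:count, l)) - 0.025
  lo_b <- uniroot(f_lo, c(1e-8, 50), tol = 1e-12)$root
  hi_b <- uniroot(f_hi, c(1e-8, 50), tol = 1e-12)$root
  ci3 <- exact_poisson_ci(3, 1)
  expect_equal(unname(ci3[1]), lo_b, tolerance = 1e-8)
  expect_equal(unname(ci3[2]), hi_b, tolerance = 1e-8)

  # widening level widens the interval monotonically
  ci90 <- exact_poisson_ci(5, 2, level = 0.90)
  ci99 <- exact_poisson_ci(5, 2, level = 0.99)
  expect_lt(ci99[1], ci90[1]); expect_gt(ci99[2], ci90[2])
})

test_that("route_rate_ci switches methods at the documented boundary", {
  expect_identical(route_rate_ci(5, 100)$method, "exact_poisson")
  expect_identical(route_rate_ci(2, 100)$method, "exact_poisson")
  expect_identical(route_rate_ci(6, 100)$method, "byar")
  est <- route_rate_ci(6, 100, scale = 1000)
  expect_equal(est$estimate, 60)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
})

test_that("fit_rate_glm reproduces crude rates and their closed forms", {
  # saturated Poisson: MLE is the crude rate
  f1 <- fit_rate_glm(30, 1000, family = "poisson")
  expect_equal(f1$rates, 0.03, tolerance = 1e-8)
  # two groups: group-indicator GLM returns each group's crude rate
  f2 <- fit_rate_glm(c(30, 12), c(1000, 600), family = "poisson",
                     groups = c("a", "b"))
  expect_equal(f2$rates, c(0.03, 0.02), tolerance = 1e-8)
  # binomial: logit-scale estimate is logit(y/m)
  f3 <- fit_rate_glm(25, 100, family = "binomial")
  expect_equal(unname(f3$estimates), qlogis(0.25), tolerance = 1e-8)
  expect_warning(f0 <- fit_rate_glm(c(3, 0), c(100, 0), family = "poisson"))
  expect_length(f0$rates, 1)
})

test_that("delta_method_ci matches the textbook log-rate interval", {
  # saturated one-group Poisson: CI = exp(log rate -/+ z/sqrt(count))
  count <- 30; expo <- 1000
  f <- fit_rate_glm(count, expo, family = "poisson")
  dm <- delta_method_ci(f$estimates, f$vcov, transform = "exp")
  z <- qnorm(0.975)
  expect_equal(dm$ci_low, exp(log(count / expo) - z / sqrt(count)),
               tolerance = 1e-10)
  expect_equal(dm$ci_high, exp(log(count / expo) + z / sqrt(count)),
               tolerance = 1e-10)
  # first-order delta SE on the natural scale: e^theta * sqrt(v)
  expect_equal(dm$se, exp(f$estimates[[1]]) * sqrt(f$vcov[1, 1]),
               tolerance = 1e-10)

  # identity transform: symmetric half-width z * sigma
  dmi <- delta_method_ci(2, matrix(0.25), transform = "identity")
  expect_equal(dmi$ci_high - dmi$estimate, z * 0.5, tolerance = 1e-12)
  # zero variance collapses the interval
  dm0 <- delta_method_ci(1, matrix(0), transform = "exp")
  expect_equal(dm0$ci_low, dm0$ci_high)
  expect_error(delta_method_ci(c(0, 0), matrix(c(1, 2, 2, 1), 2, 2)))
})

test_that("child_mortality_4q1 composes segment probabilities", {
  expect_equal(child_mortality_4q1(c(0, 0, 0, 0)), 0)
  expect_equal(child_mortality_4q1(c(1, 1, 1, 1)), 1000)
  expect_equal(child_mortality_4q1(rep(0.01, 4)), 1000 * (1 - 0.99^4))
  expect_equal(child_mortality_4q1(rep(0.01, 4)), 39.40399, tolerance = 1e-5)
  # monotone nondecreasing in each segment
  base <- c(0.02, 0.01, 0.015, 0.005)
  v0 <- child_mortality_4q1(base)
  for (j in 1:4) {
    up <- base; up[j] <- up[j] + 0.01
    expect_gte(child_mortality_4q1(up), v0)
  }
  expect_error(child_mortality_4q1(c(0.1, 0.2, 0.3)))
  expect_error(child_mortality_4q1(c(0.1, 0.2, 0.3, 1.4)))
})

test_that("relative_ci_width is the CI width over the estimate", {
  est <- data.frame(estimate = 0.2, ci_low = 0.1, ci_high = 0.3)
  expect_equal(relative_ci_width(est), 1.0)
  expect_equal(relative_ci_width(data.frame(estimate = 5, ci_low = 5,
                                            ci_high = 5)), 0)
  # composition with the Wilson interval
  ci <- wilson_ci(5, 22)
  est5 <- data.frame(estimate = 5 / 22, ci_low = ci[[1]], ci_high = ci[[2]])
  expect_equal(relative_ci_width(est5), (ci[[2]] - ci[[1]]) / (5 / 22))
  expect_warning(w <- relative_ci_width(data.frame(estimate = 0, ci_low = 0,
                                                   ci_high = 0.1)))
  expect_true(is.na(w))
})

test_that("district_estimates routes families and orders output", {
  tab <- data.frame(district_id = c(1, 2, 3, 4),
                    events = c(5, 30, 2, 40),
                    exposure = c(22, 4000, 900, 2000),
                    family = c("proportion", "rate", "rate",
                               "rate_glm_poisson"))
  out <- district_estimates(tab, scale = 1)
  expect_identical(out$district_id, tab$district_id)
  expect_identical(out$method, c("wilson", "byar", "exact_poisson",
                                 "delta_poisson"))
  expect_true(all(out$ci_low <= out$estimate & out$estimate <= out$ci_high))
  expect_true(all(out$rel_width > 0))
})
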