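#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval: nonzero width at `y = 0` and `y = m`,
#' bounds always inside \[0, 1\]. This is the interval used for district
#' proportions of rare-event indicators such as teenage pregnancies.
#'
#' @param y Event count, `0 <= y <= m`.
#' @param m Number of trials (>= 1).
#' @param level Confidence level.
#' @return `c(lo, hi)`.
#' @export
wilson_ci <- function(y, m, level = 0.95) {
  if (m < 1) stop("m must be >= 1")
  if (y < 0 || y > m) stop("y must be in [0, m]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- y / m
  denom <- 1 + z^2 / m
  center <- (phat + z^2 / (2 * m)) / denom
  half <- z * sqrt(phat * (1 - phat) / m + z^2 / (4 * m^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Byar's approximation to Poisson rate confidence limits
#'
#' Cube-root normal approximation to the exact Poisson limits, accurate for
#' moderate counts (used for counts above 5):
#' `lo = count (1 - 1/(9 count) - z/(3 sqrt(count)))^3 / denominator` and
#' `hi = (count + 1) (1 - 1/(9 (count+1)) + z/(3 sqrt(count+1)))^3 /
#' denominator`.
#'
#' @param count Event count (> 5 for the published routing; see
#'   [route_rate_ci()]).
#' @param denominator Exposure (person-years, births, ...), > 0.
#' @param level Confidence level.
#' @return `c(lo, hi)` on the rate scale (events per unit denominator).
#' @export
byar_ci <- function(count, denominator, level = 0.95) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (count <= 0) stop("count must be positive for Byar's approximation")
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- count * (1 - 1 / (9 * count) - z / (3 * sqrt(count)))^3
  cp1 <- count + 1
  hi <- cp1 * (1 - 1 / (9 * cp1) + z / (3 * sqrt(cp1)))^3
  c(lo = lo / denominator, hi = hi / denominator)
}

#' Exact Poisson rate confidence limits
#'
#' Exact (Garwood) limits via the gamma/chi-square relation: the lower limit
#' solves `P(X >= count | lambda = lo * denominator) = alpha/2` and the
#' upper solves `P(X <= count | lambda = hi * denominator) = alpha/2`
#' (`lo = 0` when `count = 0`). Computed, replacing printed exact-probability
#' tables, and identical to them by construction.
#'
#' @param count Event count (>= 0).
#' @param denominator Exposure, > 0.
#' @param level Confidence level.
#' @return `c(lo, hi)` on the rate scale.
#' @export
exact_poisson_ci <- function(count, denominator, level = 0.95) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (count < 0) stop("count must be >= 0")
  alpha <- 1 - level
  lo <- if (count == 0) 0 else stats::qgamma(alpha / 2, count)
  hi <- stats::qgamma(1 - alpha / 2, count + 1)
  c(lo = lo / denominator, hi = hi / denominator)
}

#' Route a rate to Byar's or the exact Poisson interval by count
#'
#' Counts above 5 use Byar's approximation; counts of 5 or fewer use the
#' exact Poisson limits (the boundary count of exactly 5 is routed to the
#' exact method — the conservative choice).
#'
#' @param count Event count.
#' @param denominator Exposure.
#' @param level Confidence level.
#' @param district_id Optional id carried into the result.
#' @param scale Report per `scale` units (1 = raw rate; 1000 for per-1000
#'   rates).
#' @return A one-row `district_estimate` data frame: `district_id`,
#'   `estimate`, `ci_low`, `ci_high`, `rel_width`, `method`.
#' @export
route_rate_ci <- function(count, denominator, level = 0.95,
                          district_id = NA_integer_, scale = 1) {
  if (count > 5) {
    ci <- byar_ci(count, denominator, level)
    method <- "byar"
  } else {
    ci <- exact_poisson_ci(count, denominator, level)
    method <- "exact_poisson"
  }
  est <- count / denominator
  district_estimate(district_id, est * scale, ci[1] * scale, ci[2] * scale,
                    method)
}

district_estimate <- function(district_id, estimate, ci_low, ci_high,
                              method) {
  data.frame(district_id = district_id, estimate = estimate,
             ci_low = ci_low, ci_high = ci_high,
             rel_width = if (estimate > 0) (ci_high - ci_low) / estimate
                         else NA_real_,
             method = method)
}

#' Per-group rate GLM (Poisson with log exposure offset, or binomial)
#'
#' Fits a saturated group-indicator GLM — Poisson with `log(exposure)`
#' offset for fertility-style rates, binomial for mortality-style rates —
#' and returns the link-scale estimates with their variance-covariance
#' matrix, for delta-method interval construction.
#'
#' @param occurrences Event counts per group.
#' @param exposure Person-years (Poisson) or trials (binomial) per group.
#' @param family `"poisson"` or `"binomial"`.
#' @param groups Group labels (default one group per element).
#' @return List with `groups`, `estimates` (link scale), `vcov`, `rates`
#'   (natural scale), `family`, and the fitted `glm` object.
#' @export
fit_rate_glm <- function(occurrences, exposure,
                         family = c("poisson", "binomial"),
                         groups = seq_along(occurrences)) {
  family <- match.arg(family)
  if (any(occurrences < 0)) stop("occurrences must be non-negative")
  keep <- exposure > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " group(s) with zero exposure")
    occurrences <- occurrences[keep]; exposure <- exposure[keep]
    groups <- groups[keep]
  }
  g <- factor(groups, levels = unique(groups))
  # single group: the saturated model is intercept-only
  rhs <- if (nlevels(g) > 1) "0 + g" else "1"
  ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  if (family == "poisson") {
    fit <- stats::glm(stats::as.formula(
      paste("occurrences ~", rhs, "+ offset(log(exposure))")),
      family = stats::poisson(), control = ctl)
    rates <- exp(stats::coef(fit))
  } else {
    fit <- stats::glm(stats::as.formula(
      paste("cbind(occurrences, exposure - occurrences) ~", rhs)),
      family = stats::binomial(), control = ctl)
    rates <- stats::plogis(stats::coef(fit))
  }
  est <- stats::coef(fit)
  names(est) <- names(rates) <- levels(g)
  list(groups = levels(g), estimates = est, vcov = stats::vcov(fit),
       rates = unname(rates), family = family, fit = fit)
}

#' Delta-method confidence intervals for transformed estimates
#'
#' Propagates link-scale standard errors through a differentiable transform.
#' The natural-scale standard error is the first-order delta value
#' `|t'(theta)| * se(theta)`; the interval itself is built symmetrically on
#' the link scale and then transformed, which keeps rate intervals
#' non-negative and probability intervals inside \[0, 1\].
#'
#' @param estimates Link-scale estimates (vector).
#' @param vcov Variance-covariance matrix of the estimates.
#' @param transform `"exp"` (log-link rates), `"invlogit"`, or
#'   `"identity"`.
#' @param level Confidence level.
#' @return Data frame with `estimate` (natural scale), `se` (delta-method,
#'   natural scale), `ci_low`, `ci_high`.
#' @export
delta_method_ci <- function(estimates, vcov, transform = c("exp", "invlogit",
                                                           "identity"),
                            level = 0.95) {
  transform <- match.arg(transform)
  vcov <- as.matrix(vcov)
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("vcov is not positive semi-definite")
  se_link <- sqrt(pmax(diag(vcov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tfun <- switch(transform, exp = exp, invlogit = stats::plogis,
                 identity = identity)
  grad <- switch(transform,
                 exp = exp(estimates),
                 invlogit = stats::plogis(estimates) *
                   (1 - stats::plogis(estimates)),
                 identity = rep(1, length(estimates)))
  data.frame(estimate = tfun(estimates),
             se = abs(grad) * se_link,
             ci_low = tfun(estimates - z * se_link),
             ci_high = tfun(estimates + z * se_link))
}

#' Synthetic-cohort child mortality rate (4q1)
#'
#' Combines the death probabilities of the age segments 12-23, 24-35, 36-47
#' and 48-59 months into the probability of dying between the first and
#' fifth birthday, per 1000 children surviving their first birthday:
#' `1000 * (1 - prod(1 - q_j))`.
#'
#' @param segments Numeric vector (or list) of the four segment
#'   probabilities, each in \[0, 1\].
#' @return Rate per 1000.
#' @export
child_mortality_4q1 <- function(segments) {
  q <- unlist(segments, use.names = FALSE)
  if (length(q) != 4) stop("four age-segment probabilities are required")
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("segment probabilities must be in [0, 1]")
  1000 * (1 - prod(1 - q))
}

#' Relative confidence-interval width
#'
#' The uncertainty metric attached to district estimates: the difference
#' between the upper and lower 95% confidence limits relative to the point
#' estimate. Smaller is more precise. Undefined (returned as `NA` with a
#' warning) for a zero estimate.
#'
#' @param est A one-row `district_estimate` data frame (or any list with
#'   `estimate`, `ci_low`, `ci_high`).
#' @return Scalar relative width.
#' @export
relative_ci_width <- function(est) {
  if (!all(c("estimate", "ci_low", "ci_high") %in% names(est)))
    stop("est must carry estimate, ci_low, ci_high")
  if (est$estimate <= 0) {
    if (est$estimate < 0) stop("estimate must be >= 0")
    warning("zero estimate: relative CI width undefined")
    return(NA_real_)
  }
  (est$ci_high - est$ci_low) / est$estimate
}

#' District-level estimates table
#'
#' Applies the appropriate interval method to each district row of an input
#' table: `indicator` family `"proportion"` uses the Wilson score interval
#' on `events / exposure`; `"rate"` routes to Byar's or the exact Poisson
#' interval by count; `"rate_glm_poisson"` and `"rate_glm_binomial"` fit the
#' per-district saturated GLM and use delta-method intervals.
#'
#' @param districts Data frame with columns `district_id`, `events`,
#'   `exposure`, and `family` (one of the values above; recycled if a single
#'   value is given).
#' @param level Confidence level.
#' @param scale Report estimates per `scale` units (e.g. 1000).
#' @return A `district_estimate` data frame, one row per district.
#' @export
district_estimates <- function(districts, level = 0.95, scale = 1) {
  need <- c("district_id", "events", "exposure")
  if (!all(need %in% names(districts)))
    stop("districts needs columns: ", paste(need, collapse = ", "))
  fam <- if ("family" %in% names(districts)) districts$family else "proportion"
  fam <- rep_len(fam, nrow(districts))
  out <- NULL
  glm_rows <- fam %in% c("rate_glm_poisson", "rate_glm_binomial")
  for (i in which(!glm_rows)) {
    row <- districts[i, ]
    if (fam[i] == "proportion") {
      ci <- wilson_ci(row$events, row$exposure, level)
      est <- district_estimate(row$district_id,
                               row$events / row$exposure * scale,
                               ci[1] * scale, ci[2] * scale, "wilson")
    } else if (fam[i] == "rate") {
      est <- route_rate_ci(row$events, row$exposure, level,
                           district_id = row$district_id, scale = scale)
    } else stop("unknown family: ", fam[i])
    out <- rbind(out, est)
  }
  for (fm in c("rate_glm_poisson", "rate_glm_binomial")) {
    idx <- which(fam == fm)
    if (!length(idx)) next
    fit <- fit_rate_glm(districts$events[idx], districts$exposure[idx],
                        family = sub("rate_glm_", "", fm),
                        groups = districts$district_id[idx])
    dm <- delta_method_ci(fit$estimates, fit$vcov,
                          transform = if (fm == "rate_glm_poisson") "exp"
                                      else "invlogit",
                          level = level)
    out <- rbind(out, district_estimate(
      districts$district_id[idx], dm$estimate * scale,
      dm$ci_low * scale, dm$ci_high * scale,
      sub("rate_glm", "delta", fm)))
  }
  out <- out[order(match(out$district_id, districts$district_id)), ]
  rownames(out) <- NULL
  out
}
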