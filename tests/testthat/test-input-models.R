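test_that("logit-linear fit recovers transform-linear truth exactly", {
  ages <- 20:90
  p <- plogis(-6 + 0.08 * ages)
  cs <- prevalence_cross_section(2009, ages, p)
  fit <- fit_logit_linear_prevalence(cs, age_range = c(15, 100))
  expect_equal(fit$intercept, -6, tolerance = 1e-8)
  expect_equal(fit$slope, 0.08, tolerance = 1e-10)
  expect_equal(predict(fit, ages), p, tolerance = 1e-10)
  expect_equal(fit$transform, "logit")
  expect_equal(fit$year, 2009)

  flat <- fit_logit_linear_prevalence(
    prevalence_cross_section(2009, ages, rep(0.5, length(ages))))
  expect_equal(flat$intercept, 0, tolerance = 1e-12)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("log-linear fit recovers transform-linear truth exactly", {
  ages <- 20:90
  i <- exp(-9 + 0.06 * ages)
  fit <- fit_log_linear_incidence(rate_schedule(2012, ages, i,
                                                kind = "incidence"))
  expect_equal(fit$intercept, -9, tolerance = 1e-8)
  expect_equal(fit$slope, 0.06, tolerance = 1e-10)
  expect_true(all(predict(fit, seq(0, 120, 5)) > 0))

  const <- fit_log_linear_incidence(
    rate_schedule(2012, ages, rep(0.02, length(ages)), kind = "incidence"))
  expect_equal(const$intercept, log(0.02), tolerance = 1e-12)
  expect_equal(const$slope, 0, tolerance = 1e-12)
})

test_that("fits agree with the textbook normal equations and recover noisy truth", {
  ages <- 20:90
  p_true <- plogis(-6 + 0.08 * ages)
  set.seed(11)
  p_obs <- rbinom(length(ages), 1e5, p_true) / 1e5
  fit <- fit_logit_linear_prevalence(prevalence_cross_section(2009, ages, p_obs))

  # independent oracle: normal equations on the transformed data
  X <- cbind(1, ages)
  y <- qlogis(p_obs)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - 2)
  vc <- s2 * solve(t(X) %*% X)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$coef_covariance, unname(vc), tolerance = 1e-10)

  # coefficients within 4 standard errors of the generating truth
  expect_lt(abs(fit$intercept - (-6)) / sqrt(vc[1, 1]), 4)
  expect_lt(abs(fit$slope - 0.08) / sqrt(vc[2, 2]), 4)

  i_true <- exp(-9 + 0.06 * ages)
  set.seed(12)
  i_obs <- rpois(length(ages), i_true * 1e6) / 1e6
  fil <- fit_log_linear_incidence(rate_schedule(2012, ages, i_obs,
                                                kind = "incidence"))
  expect_lt(abs(fil$intercept - (-9)) / sqrt(fil$coef_covariance[1, 1]), 4)
  expect_lt(abs(fil$slope - 0.06) / sqrt(fil$coef_covariance[2, 2]), 4)
})

test_that("boundary values are dropped or rejected as configured", {
  ages <- 20:30
  p <- c(0, plogis(-6 + 0.08 * ages[-1]))
  cs <- prevalence_cross_section(2009, ages, p)
  fit <- fit_logit_linear_prevalence(cs)
  expect_equal(fit$n_obs, length(ages) - 1)
  expect_error(fit_logit_linear_prevalence(cs, drop_boundary = FALSE),
               "logit undefined")
  expect_error(
    fit_logit_linear_prevalence(
      prevalence_cross_section(2009, 50:51, c(0.1, 0.2))),
    "insufficient data")
  sch <- rate_schedule(2012, ages, c(0, exp(-9 + 0.06 * ages[-1])),
                       kind = "incidence")
  expect_error(fit_log_linear_incidence(sch, drop_boundary = FALSE),
               "log undefined")
})

test_that("cohort derivative is exact on a logit-affine surface", {
  # surface logit p = -6 + 0.08 a + 0.01 t (t relative to 2009)
  mk <- function(year) {
    m <- fit_logit_linear_prevalence(prevalence_cross_section(
      year, 20:90, plogis(-6 + 0.08 * (20:90) + 0.01 * (year - 2009))))
    m
  }
  m0 <- mk(2009); m1 <- mk(2015)
  p60 <- plogis(-6 + 0.08 * 60 + 0.01 * 3)
  dp60 <- p60 * (1 - p60) * (0.08 + 0.01)
  cd <- cohort_derivative(m0, m1, age_mid = 60, method = "analytic")
  expect_equal(cd$p, p60, tolerance = 1e-9)
  expect_equal(cd$dp, dp60, tolerance = 1e-9)
  # the symmetric natural-scale difference is second-order accurate only:
  # close to, but not exactly, the analytic directional derivative
  fd <- cohort_derivative(m0, m1, age_mid = 60,
                          method = "finite_difference")
  expect_equal(fd$dp, dp60, tolerance = 0.02)
  expect_equal(fd$p, (plogis(-6 + 0.08 * 57) +
                        plogis(-6 + 0.08 * 63 + 0.01 * 6)) / 2,
               tolerance = 1e-9)
})

test_that("cohort derivative handles constant surfaces per definition", {
  mk_const <- function(year, p) {
    fit_logit_linear_prevalence(
      prevalence_cross_section(year, 20:90, rep(p, 71)))
  }
  same <- cohort_derivative(mk_const(2009, 0.1), mk_const(2015, 0.1), 50)
  expect_equal(same$dp, 0, tolerance = 1e-12)
  expect_equal(same$p, 0.1, tolerance = 1e-10)

  # pure calendar-time change, finite-difference reading: (0.16-0.10)/6
  fd <- cohort_derivative(mk_const(2009, 0.10), mk_const(2015, 0.16), 50,
                          method = "finite_difference")
  expect_equal(fd$dp, 0.01, tolerance = 1e-10)
  expect_equal(fd$p, 0.13, tolerance = 1e-10)
  # analytic reading differentiates the logit-interpolated surface
  an <- cohort_derivative(mk_const(2009, 0.10), mk_const(2015, 0.16), 50)
  expect_equal(an$dp, an$p * (1 - an$p) * (qlogis(0.16) - qlogis(0.10)) / 6,
               tolerance = 1e-10)

  expect_error(cohort_derivative(mk_const(2015, 0.1), mk_const(2009, 0.1), 50),
               "t1 > t0")
})

test_that("mortality lookup interpolates linearly and guards its span", {
  ms <- rate_schedule(2012, c(40, 50, 60), c(0.01, 0.02, 0.05),
                      kind = "mortality")
  expect_equal(mortality_at(ms, 50), 0.02)
  expect_equal(mortality_at(ms, 45), 0.015)
  expect_equal(mortality_at(ms, c(40, 55, 60)), c(0.01, 0.035, 0.05))
  expect_error(mortality_at(ms, 39), "outside schedule span")

  # dense Gompertz schedule: interpolation error < 1e-4 relative
  ages <- seq(30, 90, 0.25)
  gomp <- rate_schedule(2012, ages, 1e-5 * exp(0.1 * ages), kind = "mortality")
  probe <- seq(30.1, 89.9, 0.37)
  expect_lt(max(abs(mortality_at(gomp, probe) / (1e-5 * exp(0.1 * probe)) - 1)),
            1e-4)
})

test_that("schedule constructors validate their invariants", {
  expect_error(prevalence_cross_section(2009, c(50, 50), c(0.1, 0.2)),
               "unique")
  expect_error(prevalence_cross_section(2009, 50:51, c(0.1, 1.2)),
               "\\[0, 1\\]")
  expect_error(rate_schedule(2012, 50:51, c(0.1, -0.2), kind = "incidence"),
               "nonnegative")
})
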