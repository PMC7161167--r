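make_fits <- function(seed = 1) {
  sc <- scenario_constant_ratio()
  ins <- simulate_inputs(sc, seed = seed)
  c(fit_inputs(ins), list(mort = ins$mortality))
}

zero_cov <- function(f) { f$coef_covariance <- matrix(0, 2, 2); f }

test_that("zero-variance inputs collapse the PSA onto the point estimate", {
  f <- make_fits()
  f0 <- zero_cov(f$f0); f1 <- zero_cov(f$f1); fi <- zero_cov(f$fi)
  ages <- seq(40, 90, 5)
  res <- run_psa(f0, f1, fi, f$mort, psa_config(ages, n_draws = 50, seed = 3))
  pt <- estimate_point(f0, f1, fi, f$mort, ages)
  rr <- res$summary[res$summary$outcome == "rate_ratio", ]
  expect_equal(rr$median, pt$rate_ratio, tolerance = 1e-12)
  expect_equal(rr$lo, pt$rate_ratio, tolerance = 1e-12)
  expect_equal(rr$hi, pt$rate_ratio, tolerance = 1e-12)
  dm <- res$summary[res$summary$outcome == "delta_m", ]
  expect_equal(dm$median, pt$delta_m, tolerance = 1e-12)
})

test_that("a single draw is its own median and interval", {
  f <- make_fits()
  res <- run_psa(f$f0, f$f1, f$fi, f$mort,
                 psa_config(c(50, 70), n_draws = 1, seed = 8))
  s <- res$summary
  expect_equal(s$median, s$lo)
  expect_equal(s$median, s$hi)
})

test_that("identical configurations reproduce the PSA bitwise", {
  f <- make_fits()
  cfg <- psa_config(seq(45, 85, 10), n_draws = 100, seed = 21)
  a <- run_psa(f$f0, f$f1, f$fi, f$mort, cfg)
  b <- run_psa(f$f0, f$f1, f$fi, f$mort, cfg)
  expect_identical(a, b)
  c2 <- run_psa(f$f0, f$f1, f$fi, f$mort,
                psa_config(seq(45, 85, 10), n_draws = 100, seed = 22))
  expect_false(identical(a$summary, c2$summary))
})

test_that("coefficient draws follow the fitted covariance", {
  f <- make_fits()
  expect_identical(
    sample_input_models(zero_cov(f$f0), zero_cov(f$f1), zero_cov(f$fi)),
    sample_input_models(zero_cov(f$f0), zero_cov(f$f1), zero_cov(f$fi)))
  d1 <- sample_input_models(zero_cov(f$f0), zero_cov(f$f1), zero_cov(f$fi))
  expect_equal(d1$prev_t0$intercept, f$f0$intercept)
  expect_equal(d1$inc$slope, f$fi$slope)

  # law of large numbers: empirical covariance within 5% relative
  model <- f$f0
  model$coef_covariance <- matrix(c(4e-4, -6e-6, -6e-6, 1e-7), 2)
  set.seed(31)
  draws <- matrix(0, 1e5, 2)
  for (k in seq_len(1e5)) {
    d <- sample_input_models(model, model, model)$prev_t0
    draws[k, ] <- c(d$intercept, d$slope)
  }
  emp <- cov(draws)
  expect_lt(max(abs(emp / model$coef_covariance - 1)), 0.05)
})

test_that("quantile ordering holds at every age and outcome", {
  f <- make_fits()
  res <- run_psa(f$f0, f$f1, f$fi, f$mort,
                 psa_config(seq(40, 90, 2), n_draws = 200, seed = 5))
  expect_true(all(res$summary$lo <= res$summary$median + 1e-12))
  expect_true(all(res$summary$median <= res$summary$hi + 1e-12))
  expect_true(all(res$flag_counts[-1] <= res$n_draws))
})

test_that("inflating input covariances never narrows the intervals", {
  f <- make_fits()
  cfg <- psa_config(seq(45, 90, 5), n_draws = 500, seed = 12)
  base <- run_psa(f$f0, f$f1, f$fi, f$mort, cfg, covariance_scale = 1)
  wide <- run_psa(f$f0, f$f1, f$fi, f$mort, cfg, covariance_scale = 4)
  w_base <- base$summary$hi - base$summary$lo
  w_wide <- wide$summary$hi - wide$summary$lo
  expect_true(all(w_wide >= w_base * (1 - 0.02)))
})

test_that("draws on a singular denominator are counted, not fatal", {
  # constant p = 0.1, dp = 0, i = m exactly: the denominator is exactly 0
  flat <- function(year) {
    f <- fit_logit_linear_prevalence(
      prevalence_cross_section(year, 20:60, rep(0.1, 41)))
    f$intercept <- qlogis(0.1); f$slope <- 0
    zero_cov(f)
  }
  inc <- zero_cov(fit_log_linear_incidence(
    rate_schedule(2012, 20:60, rep(0.01, 41), kind = "incidence")))
  inc$intercept <- log(0.01); inc$slope <- 0
  mort <- rate_schedule(2012, 20:60, rep(exp(log(0.01)), 41),
                        kind = "mortality")
  res <- run_psa(flat(2009), flat(2015), inc, mort,
                 psa_config(c(30, 50), n_draws = 20, seed = 2))
  rr <- res$summary[res$summary$outcome == "rate_ratio", ]
  expect_true(all(is.nan(rr$median)))
  expect_equal(res$flag_counts$n_nonfinite, c(20, 20))
  # delta_m is still finite: i - dp/(1-p) = i
  dm <- res$summary[res$summary$outcome == "delta_m", ]
  expect_equal(dm$median, rep(0.1, 2), tolerance = 1e-10)
})

test_that("age-group aggregation equals the representative-age summaries", {
  f <- make_fits()
  ages <- c(40, 42, 47, 52, 57, 62, 67, 72, 77, 82, 87, 92.5)
  res <- run_psa(f$f0, f$f1, f$fi, f$mort,
                 psa_config(ages, n_draws = 150, seed = 4))

  single <- aggregate_age_groups(
    res, data.frame(lo = c(40, 42), hi = c(40, 42)))
  rr <- res$summary[res$summary$outcome == "rate_ratio" &
                      res$summary$age %in% c(40, 42), ]
  srr <- single[single$outcome == "rate_ratio", ]
  expect_equal(srr$median, rr$median)
  expect_equal(srr$lo, rr$lo)

  groups <- rbind(data.frame(lo = seq(40, 85, 5), hi = seq(44, 89, 5)),
                  data.frame(lo = 90, hi = Inf))
  grouped <- aggregate_age_groups(res, groups)
  g17 <- grouped[grouped$label == "40-44" & grouped$outcome == "rate_ratio", ]
  expect_equal(g17$representative_age, 42)
  expect_equal(g17$median, rr$median[rr$age == 42])
  open <- grouped[grouped$label == "90+", ]
  expect_true(all(open$representative_age == 92.5))

  expect_error(aggregate_age_groups(res, data.frame(lo = 1, hi = 2)[0, ]),
               "empty")
  expect_error(aggregate_age_groups(res,
                                    data.frame(lo = c(40, 44), hi = c(45, 50))),
               "non-overlapping")
  expect_error(aggregate_age_groups(res, data.frame(lo = 41, hi = 42)),
               "not on the PSA grid")
})

test_that("psa_config validates its fields", {
  expect_error(psa_config(c(50, 40)), "strictly increasing")
  expect_error(psa_config(40:50, n_draws = 0), "n_draws")
  expect_error(psa_config(40:50, quantiles = c(0.6, 0.9)), "quantiles")
})
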