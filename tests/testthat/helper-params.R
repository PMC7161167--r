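# random smooth illness-death parameter sets for property-style tests:
# log-linear incidence, Gompertz non-diseased mortality, constant ratio
random_idm_params <- function(seed) {
  set.seed(seed)
  c0 <- runif(1, -12, -8)
  c1 <- runif(1, 0.03, 0.09)
  a0 <- 10^runif(1, -5, -4)
  b  <- runif(1, 0.07, 0.11)
  r  <- runif(1, 1.2, 4)
  list(
    params = idm_params(
      incidence = function(a) exp(c0 + c1 * a),
      mortality_nondiseased = function(a) a0 * exp(b * a),
      mortality_diseased = function(a) r * a0 * exp(b * a)),
    incidence = function(a) exp(c0 + c1 * a),
    m0 = function(a) a0 * exp(b * a),
    m1 = function(a) r * a0 * exp(b * a),
    ratio = r)
}

# fit the three input models and run the point-estimate pass on a
# simulated input set
fit_inputs <- function(ins, age_range = c(15, 100)) {
  list(f0 = fit_logit_linear_prevalence(ins$prev_t0, age_range = age_range),
       f1 = fit_logit_linear_prevalence(ins$prev_t1, age_range = age_range),
       fi = fit_log_linear_incidence(ins$incidence, age_range = age_range))
}

point_pipeline <- function(ins, ages, ...) {
  f <- fit_inputs(ins)
  estimate_point(f$f0, f$f1, f$fi, ins$mortality, ages, ...)
}
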