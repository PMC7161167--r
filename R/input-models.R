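#' Transform-linear input models
#'
#' The estimators consume smooth age-specific inputs.  Observed schedules
#' are therefore modelled by ordinary least squares on a transformed scale:
#' prevalence by a linear model in age after a logit transformation,
#' incidence after a log transformation.  The fitted coefficient pair and
#' its OLS covariance matrix are the input distribution of the
#' probabilistic sensitivity analysis.
#'
#' @name input-models
NULL

.logit <- function(p) log(p / (1 - p))
.expit <- function(x) 1 / (1 + exp(-x))

#' Age-specific prevalence cross-section
#'
#' @param year calendar year of the cross-section.
#' @param age vector of ages in years (unique).
#' @param p prevalence proportions in \[0, 1\].
#' @param n optional sampling denominators (persons per age).
#' @return An object of class `prevalence_cross_section`: a data.frame with
#'   columns `age`, `p` (and `n`), plus a `year` attribute.
#' @export
prevalence_cross_section <- function(year, age, p, n = NULL) {
  stopifnot(length(age) == length(p))
  if (anyDuplicated(age)) stop("ages must be unique", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]", call. = FALSE)
  d <- data.frame(age = as.numeric(age), p = as.numeric(p))
  if (!is.null(n)) {
    if (any(n < 1)) stop("denominators must be >= 1", call. = FALSE)
    d$n <- as.numeric(n)
  }
  d <- d[order(d$age), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, year = year, class = c("prevalence_cross_section", "data.frame"))
}

#' Age-specific rate schedule (incidence or general mortality)
#'
#' @param year calendar year of the schedule.
#' @param age vector of ages in years (unique).
#' @param rate rates per person-year (nonnegative).
#' @param py optional person-years of exposure per age.
#' @param kind `"incidence"` or `"mortality"`.
#' @return An object of class `rate_schedule`: a data.frame with columns
#'   `age`, `rate` (and `py`), plus `year` and `kind` attributes.
#' @export
rate_schedule <- function(year, age, rate, py = NULL,
                          kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  stopifnot(length(age) == length(rate))
  if (anyDuplicated(age)) stop("ages must be unique", call. = FALSE)
  if (any(rate < 0)) stop("rates must be nonnegative", call. = FALSE)
  d <- data.frame(age = as.numeric(age), rate = as.numeric(rate))
  if (!is.null(py)) {
    if (any(py <= 0)) stop("person-years must be positive", call. = FALSE)
    d$py <- as.numeric(py)
  }
  d <- d[order(d$age), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, year = year, kind = kind,
            class = c("rate_schedule", "data.frame"))
}

## shared OLS backend: y_trans ~ age via stats::lm
.fit_transform_linear <- function(age, y, transform, year, weights = NULL) {
  if (length(age) < 3L)
    stop("insufficient data: need at least 3 usable records", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(y ~ age)
         else stats::lm(y ~ age, weights = weights)
  cf <- stats::coef(fit)
  structure(list(transform = transform,
                 intercept = unname(cf[1]),
                 slope = unname(cf[2]),
                 ## suppressWarnings: summary.lm warns on the (legitimate)
                 ## zero-residual case of exactly transform-linear data
                 coef_covariance = unname(suppressWarnings(stats::vcov(fit))),
                 n_obs = length(age),
                 year = year),
            class = "transform_linear_model")
}

#' Fit a logit-linear model to an age-specific prevalence cross-section
#'
#' Ordinary least squares of `logit(p)` on age.  Records with p outside the
#' open interval (0, 1) cannot be transformed: with `drop_boundary = TRUE`
#' (default) they are dropped from the fit, otherwise they raise an error.
#'
#' @param cs a [prevalence_cross_section()].
#' @param age_range optional `c(lo, hi)` restricting the fitting ages
#'   (default `c(15, 100)`).
#' @param weights optional per-record OLS weights (off by default; the
#'   standard analysis is unweighted).
#' @param drop_boundary drop records with p = 0 or p = 1 instead of
#'   erroring.
#' @return A `transform_linear_model` with fields `transform` ("logit"),
#'   `intercept`, `slope`, `coef_covariance`, `n_obs`, `year`.
#' @export
fit_logit_linear_prevalence <- function(cs, age_range = c(15, 100),
                                        weights = NULL, drop_boundary = TRUE) {
  stopifnot(inherits(cs, "prevalence_cross_section"))
  keep <- cs$age >= age_range[1] & cs$age <= age_range[2]
  d <- cs[keep, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[keep]
  usable <- d$p > 0 & d$p < 1
  if (!all(usable)) {
    if (!drop_boundary)
      stop("prevalence outside (0, 1): logit undefined at age(s) ",
           paste(d$age[!usable], collapse = ", "), call. = FALSE)
    d <- d[usable, , drop = FALSE]
    if (!is.null(w)) w <- w[usable]
  }
  .fit_transform_linear(d$age, .logit(d$p), "logit", attr(cs, "year"), w)
}

#' Fit a log-linear model to an age-specific incidence schedule
#'
#' Ordinary least squares of `log(i)` on age; zero rates cannot be
#' transformed and are dropped (or raise an error, see `drop_boundary`).
#'
#' @inheritParams fit_logit_linear_prevalence
#' @param sch a [rate_schedule()] of kind `"incidence"`.
#' @return A `transform_linear_model` with `transform = "log"`.
#' @export
fit_log_linear_incidence <- function(sch, age_range = c(15, 100),
                                     weights = NULL, drop_boundary = TRUE) {
  stopifnot(inherits(sch, "rate_schedule"))
  keep <- sch$age >= age_range[1] & sch$age <= age_range[2]
  d <- sch[keep, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[keep]
  usable <- d$rate > 0
  if (!all(usable)) {
    if (!drop_boundary)
      stop("zero rate: log undefined at age(s) ",
           paste(d$age[!usable], collapse = ", "), call. = FALSE)
    d <- d[usable, , drop = FALSE]
    if (!is.null(w)) w <- w[usable]
  }
  .fit_transform_linear(d$age, log(d$rate), "log", attr(sch, "year"), w)
}

#' @export
print.transform_linear_model <- function(x, ...) {
  cat(sprintf("%s-linear model (%s scale): %s(y) = %.6g %+.6g * age  [n = %d%s]\n",
              x$transform, x$transform, x$transform, x$intercept, x$slope,
              x$n_obs,
              if (is.null(x$year)) "" else sprintf(", year %s", x$year)))
  invisible(x)
}

#' Predict from a transform-linear model on the natural scale
#'
#' @param object a `transform_linear_model`.
#' @param age ages (years) at which to predict.
#' @param ... unused.
#' @return Predicted prevalence in (0, 1) for a logit model, predicted
#'   rate > 0 for a log model.
#' @export
predict.transform_linear_model <- function(object, age, ...) {
  eta <- object$intercept + object$slope * age
  switch(object$transform, logit = .expit(eta), log = exp(eta),
         stop("unknown transform", call. = FALSE))
}

#' Prevalence and its cohort derivative from two cross-sectional models
#'
#' Evaluates the age-specific prevalence and its directional derivative
#' `(d/dt + d/da) p` along the unit-slope cohort line of the Lexis plane
#' through (midpoint year, `age_mid`).
#'
#' With `method = "analytic"` (default) the two fitted logit lines are
#' interpolated linearly in calendar time, giving a logit surface
#' `eta(t, a)`; the prevalence is `expit(eta)` at the midpoint and the
#' derivative is the exact directional derivative of that surface,
#' `p (1 - p) * (mean of the two age slopes + (eta1(a) - eta0(a)) / (t1 -
#' t0))`.  This is exact whenever the true logit prevalence is affine in
#' age and time -- the same assumption the input models make -- and in
#' particular carries no finite-difference attenuation.
#'
#' With `method = "finite_difference"` the classical symmetric difference
#' along the cohort diagonal is used instead: with `h = (t1 - t0)/2`,
#' `dp = (p1(age_mid + h) - p0(age_mid - h)) / (t1 - t0)` and `p` is the
#' mean of the two endpoint predictions.  This is second-order accurate
#' on the natural scale and exact for surfaces affine on the natural
#' scale, but attenuates slightly (O(h^2) curvature error) when the
#' surface is logit-affine.
#'
#' @param model_t0,model_t1 logit `transform_linear_model`s fitted to the
#'   earlier and later cross-sections.
#' @param t0,t1 their calendar years (`t1 > t0`); defaults taken from the
#'   models' `year` fields.
#' @param age_mid age(s) in years at the midpoint year `(t0 + t1)/2`.
#' @param method derivative evaluation, see Details.
#' @return A data.frame with columns `age`, `p`, `dp`.
#' @export
cohort_derivative <- function(model_t0, model_t1, age_mid,
                              t0 = model_t0$year, t1 = model_t1$year,
                              method = c("analytic", "finite_difference")) {
  stopifnot(inherits(model_t0, "transform_linear_model"),
            inherits(model_t1, "transform_linear_model"))
  method <- match.arg(method)
  if (model_t0$transform != "logit" || model_t1$transform != "logit")
    stop("cohort_derivative requires two logit prevalence models", call. = FALSE)
  if (is.null(t0) || is.null(t1) || t1 <= t0)
    stop("need calendar years with t1 > t0", call. = FALSE)
  if (method == "analytic") {
    eta0 <- model_t0$intercept + model_t0$slope * age_mid
    eta1 <- model_t1$intercept + model_t1$slope * age_mid
    p <- .expit((eta0 + eta1) / 2)
    deta <- (model_t0$slope + model_t1$slope) / 2 + (eta1 - eta0) / (t1 - t0)
    data.frame(age = age_mid, p = p, dp = p * (1 - p) * deta)
  } else {
    h <- (t1 - t0) / 2
    p0 <- predict(model_t0, age_mid - h)
    p1 <- predict(model_t1, age_mid + h)
    data.frame(age = age_mid, p = (p0 + p1) / 2, dp = (p1 - p0) / (t1 - t0))
  }
}

#' Interpolate a mortality schedule at arbitrary ages
#'
#' Linear interpolation between the bracketing grid ages; exact at grid
#' ages.  Ages outside the schedule's span raise an error rather than
#' extrapolating.
#'
#' @param ms a [rate_schedule()] of kind `"mortality"` (any rate schedule
#'   is accepted).
#' @param age ages (years) at which to evaluate.
#' @return Interpolated rates per person-year.
#' @export
mortality_at <- function(ms, age) {
  stopifnot(inherits(ms, "rate_schedule"))
  rng <- range(ms$age)
  if (any(age < rng[1] - 1e-9 | age > rng[2] + 1e-9))
    stop(sprintf("age outside schedule span [%g, %g]", rng[1], rng[2]),
         call. = FALSE)
  stats::approx(ms$age, ms$rate, xout = age, rule = 1)$y
}
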