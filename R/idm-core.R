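#' Illness-death model core
#'
#' The three-state illness-death model (healthy -> diseased -> dead,
#' healthy -> dead, no remission) links the age-specific prevalence p of a
#' chronic disease to the incidence rate i and the mortality rates m0
#' (non-diseased) and m1 (diseased).  Along a birth cohort the prevalence
#' obeys
#'
#'   dp = (1 - p) * { i - p * (m1 - m0) }
#'
#' where dp denotes the directional derivative of p along the unit-slope
#' cohort line of the Lexis plane.  Given p, dp, the incidence i and the
#' general mortality m = p*m1 + (1-p)*m0, the equation can be inverted for
#' the excess mortality rate dm = m1 - m0 and the mortality rate ratio
#' R = m1/m0.  All rates are per person-year; ages are continuous years;
#' prevalence is a proportion in [0, 1].
#'
#' @name idm-core
NULL

.check_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (k in seq_along(args)) {
    if (!all(is.finite(args[[k]])))
      stop("non-finite value in '", nm[k], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Right-hand side of the cohort prevalence ODE
#'
#' Rate of change of the age-specific prevalence along a birth cohort,
#' `(1 - p) * (i - p * (m1 - m0))`.
#'
#' @param p prevalence proportion in \[0, 1\].
#' @param i incidence rate per person-year among the disease-free.
#' @param m0 mortality rate of the non-diseased, per person-year.
#' @param m1 mortality rate of the diseased, per person-year.
#' @return Rate of prevalence change per year.  Vectorised over all
#'   arguments.
#' @examples
#' prevalence_ode_rhs(0.1, i = 0.01, m0 = 0.005, m1 = 0.010)  # 0.00855
#' @export
prevalence_ode_rhs <- function(p, i, m0, m1) {
  .check_finite(p = p, i = i, m0 = m0, m1 = m1)
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]", call. = FALSE)
  (1 - p) * (i - p * (m1 - m0))
}

#' Cohort prevalence ODE in general-mortality/rate-ratio form
#'
#' Algebraically equivalent form of [prevalence_ode_rhs()] written in terms
#' of the general mortality m and the mortality rate ratio R:
#' `(1 - p) * (i - m * p * (R - 1) / (1 + p * (R - 1)))`.  The two forms
#' coincide whenever `m = p*m1 + (1-p)*m0` and `R = m1/m0`.
#'
#' @param p prevalence proportion in \[0, 1\].
#' @param i incidence rate per person-year.
#' @param m general (population-wide) mortality rate per person-year.
#' @param R mortality rate ratio m1/m0, must satisfy `1 + p*(R-1) > 0`.
#' @return Rate of prevalence change per year.
#' @export
prevalence_ode_rhs_ratio_form <- function(p, i, m, R) {
  .check_finite(p = p, i = i, m = m, R = R)
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]", call. = FALSE)
  denom <- 1 + p * (R - 1)
  if (any(denom <= 0))
    stop("degenerate parameters: 1 + p*(R-1) must be positive", call. = FALSE)
  (1 - p) * (i - m * p * (R - 1) / denom)
}

#' Illness-death model parameters
#'
#' Bundles the generating truth of a scenario: the age-specific incidence
#' rate and the two mortality rates, each as a function of age (optionally
#' of age and calendar year for non-stationary scenarios).
#'
#' @param incidence function age -> incidence rate i per person-year.
#' @param mortality_nondiseased function age -> mortality rate m0.
#' @param mortality_diseased function age -> mortality rate m1.
#' @return An object of class `idm_params`.
#' @examples
#' idm_params(function(a) 0.01, function(a) 0.005, function(a) 0.010)
#' @export
idm_params <- function(incidence, mortality_nondiseased, mortality_diseased) {
  stopifnot(is.function(incidence), is.function(mortality_nondiseased),
            is.function(mortality_diseased))
  structure(list(incidence = incidence,
                 mortality_nondiseased = mortality_nondiseased,
                 mortality_diseased = mortality_diseased),
            class = "idm_params")
}

## evaluate a rate function at (age, year); year is ignored by
## age-only functions, so stationary scenarios need no special casing
.eval_rate <- function(f, age, year = NULL) {
  v <- if (length(formals(f)) >= 2L && !is.null(year)) f(age, year) else f(age)
  if (any(!is.finite(v)) || any(v < 0))
    stop("rate function returned a negative or non-finite value", call. = FALSE)
  v
}

#' Forward integration of the cohort prevalence ODE
#'
#' Integrates the prevalence equation along age for one birth cohort with a
#' fixed-step classical 4th-order Runge-Kutta scheme and reports prevalence
#' and its analytic cohort derivative at the requested grid ages.  Used as
#' the generator and numerical oracle for the inverse estimators; the
#' estimation itself never integrates.
#'
#' @param params an [idm_params()] object.
#' @param age_start age (years) at which integration starts.
#' @param p_start prevalence at `age_start`, in \[0, 1\] (0 for an onset
#'   age below which the disease does not occur).
#' @param grid strictly increasing vector of output ages, all
#'   `>= age_start`.
#' @param step integration step in years (default 0.1).
#' @param year_start calendar year at `age_start`; when supplied and the
#'   rate functions accept two arguments, rates are evaluated along the
#'   cohort line (year advances with age).
#' @return A data.frame with columns `age`, `p`, `dp` (analytic right-hand
#'   side at each grid age).
#' @export
forward_prevalence <- function(params, age_start, p_start, grid, step = 0.1,
                               year_start = NULL) {
  stopifnot(inherits(params, "idm_params"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a positive number", call. = FALSE)
  if (p_start < 0 || p_start > 1)
    stop("'p_start' must lie in [0, 1]", call. = FALSE)
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing", call. = FALSE)
  if (any(grid < age_start - 1e-12))
    stop("'grid' must not extend below 'age_start'", call. = FALSE)

  rhs <- function(a, p) {
    yr <- if (is.null(year_start)) NULL else year_start + (a - age_start)
    prevalence_ode_rhs(min(max(p, 0), 1),
                       .eval_rate(params$incidence, a, yr),
                       .eval_rate(params$mortality_nondiseased, a, yr),
                       .eval_rate(params$mortality_diseased, a, yr))
  }

  ## classical RK4 from age_start to each grid age in turn
  p <- p_start
  a <- age_start
  out_p <- numeric(length(grid))
  for (k in seq_along(grid)) {
    target <- grid[k]
    while (a < target - 1e-12) {
      h <- min(step, target - a)
      k1 <- rhs(a, p)
      k2 <- rhs(a + h / 2, p + h / 2 * k1)
      k3 <- rhs(a + h / 2, p + h / 2 * k2)
      k4 <- rhs(a + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p <- min(max(p, 0), 1)   # nonnegative rates keep p in [0,1]; clip roundoff
      a <- a + h
    }
    out_p[k] <- p
  }
  data.frame(age = grid, p = out_p,
             dp = vapply(seq_along(grid),
                         function(k) rhs(grid[k], out_p[k]), numeric(1)))
}

#' Excess mortality rate estimator
#'
#' Inverts the cohort prevalence equation for the excess mortality rate
#' `dm = m1 - m0`:  `dm = (i - dp/(1 - p)) / p`.  Negative results are
#' returned verbatim (never clipped): downstream diagnostics flag them.
#'
#' @param p prevalence, strictly inside (0, 1).
#' @param dp cohort-direction derivative of the prevalence, per year.
#' @param i incidence rate per person-year.
#' @return Excess mortality rate per person-year.  Vectorised.
#' @export
estimate_delta_m <- function(p, dp, i) {
  .check_finite(p = p, dp = dp, i = i)
  if (any(p <= 0 | p >= 1))
    stop("singular prevalence: estimator requires 0 < p < 1", call. = FALSE)
  (i - dp / (1 - p)) / p
}

#' Mortality rate ratio estimator
#'
#' Inverts the general-mortality form of the cohort prevalence equation for
#' the mortality rate ratio `R = m1/m0`:
#' `R = 1 + (1/p) * (i*(1-p) - dp) / ((1-p)*(m-i) + dp)`.
#' Negative or very large values are returned verbatim; they signal the
#' numerical instabilities analysed by [flag_estimate()].
#'
#' @param p prevalence, strictly inside (0, 1).
#' @param dp cohort-direction derivative of the prevalence, per year.
#' @param i incidence rate per person-year.
#' @param m general mortality rate per person-year.
#' @return Dimensionless mortality rate ratio.  Vectorised.
#' @export
estimate_rate_ratio <- function(p, dp, i, m) {
  .check_finite(p = p, dp = dp, i = i, m = m)
  if (any(p <= 0 | p >= 1))
    stop("singular prevalence: estimator requires 0 < p < 1", call. = FALSE)
  denom <- (1 - p) * (m - i) + dp
  if (any(denom == 0))
    stop("singular denominator: (1-p)*(m-i) + dp is exactly zero", call. = FALSE)
  1 + (1 / p) * (i * (1 - p) - dp) / denom
}

#' General mortality from prevalence and the two state-specific rates
#'
#' `m = p*m1 + (1-p)*m0`, the prevalence-weighted population mortality.
#'
#' @param p prevalence proportion in \[0, 1\].
#' @param m0 mortality rate of the non-diseased.
#' @param m1 mortality rate of the diseased.
#' @return General mortality rate per person-year.  Vectorised.
#' @export
general_mortality <- function(p, m0, m1) {
  .check_finite(p = p, m0 = m0, m1 = m1)
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]", call. = FALSE)
  if (any(m0 < 0) || any(m1 < 0)) stop("rates must be nonnegative", call. = FALSE)
  p * m1 + (1 - p) * m0
}
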