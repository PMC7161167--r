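#' Synthetic study-input generator
#'
#' Generates complete stand-ins for the aggregated inputs of an excess
#' mortality analysis — two age-specific prevalence cross-sections a few
#' calendar years apart, one incidence schedule and one general-mortality
#' schedule at the midpoint year — from a known illness-death truth.  The
#' true prevalence surface is obtained by integrating the cohort prevalence
#' ODE; observed prevalence is binomial given per-age denominators,
#' observed incidence is Poisson given per-age person-years, and the
#' general mortality is emitted noise-free (it is treated as fixed external
#' data throughout).
#'
#' @name synthetic-data
NULL

#' Define a synthetic illness-death scenario
#'
#' @param params an [idm_params()] object: the generating truth.
#' @param t0,t1 calendar years of the two prevalence cross-sections
#'   (`t1 > t0`); the midpoint year `(t0 + t1)/2` carries the incidence and
#'   mortality schedules.
#' @param ages age grid (years) on which observations are emitted.
#' @param n per-age binomial denominators for prevalence (recycled).
#' @param py per-age person-years of exposure for incidence (recycled).
#' @param onset_age integration start age; prevalence equals `p_onset`
#'   there (0 for a disease absent before `onset_age`).
#' @param p_onset prevalence at the onset age (default 0).
#' @param step RK4 integration step in years.
#' @param seed integer seed used by [simulate_inputs()].
#' @return An object of class `idm_scenario`.
#' @export
idm_scenario <- function(params, t0, t1, ages, n, py,
                         onset_age = 10, p_onset = 0, step = 0.1, seed = 1L) {
  stopifnot(inherits(params, "idm_params"), t1 > t0)
  ages <- as.numeric(ages)
  if (is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly increasing", call. = FALSE)
  if (min(ages) < onset_age)
    stop("ages must not extend below the onset age", call. = FALSE)
  n <- rep_len(as.numeric(n), length(ages))
  py <- rep_len(as.numeric(py), length(ages))
  if (any(n < 1)) stop("denominators must be >= 1", call. = FALSE)
  if (any(py <= 0)) stop("person-years must be positive", call. = FALSE)
  if (p_onset < 0 || p_onset > 1)
    stop("'p_onset' must lie in [0, 1]", call. = FALSE)
  structure(list(params = params, t0 = t0, t1 = t1, t_mid = (t0 + t1) / 2,
                 ages = ages, n = n, py = py, onset_age = onset_age,
                 p_onset = p_onset, step = step, seed = as.integer(seed)),
            class = "idm_scenario")
}

#' True prevalence surface of a scenario
#'
#' Integrates each birth cohort (fixed `year - age`) independently from
#' prevalence 0 at the scenario's onset age, so the surface is consistent
#' with the illness-death truth by construction.  For age-only (stationary)
#' rate functions the surface does not depend on the calendar year.
#'
#' @param sc an [idm_scenario()].
#' @param step optional integration step override (default: the
#'   scenario's).
#' @return A function `(year, age) -> prevalence proportion`, vectorised
#'   over `age` for a scalar `year`.
#' @export
true_prevalence_surface <- function(sc, step = sc$step) {
  stopifnot(inherits(sc, "idm_scenario"))
  force(step)
  stationary <- all(vapply(sc$params, function(f) length(formals(f)) < 2L,
                           logical(1)))
  function(year, age) {
    age <- as.numeric(age)
    if (any(age < sc$onset_age))
      stop("requested age below the scenario onset age", call. = FALSE)
    if (stationary) {
      ## all cohorts see the same rates: one integration serves every age
      grid <- sort(unique(age))
      fp <- forward_prevalence(sc$params, age_start = sc$onset_age,
                               p_start = sc$p_onset, grid = grid, step = step)
      return(fp$p[match(age, grid)])
    }
    ## non-stationary: each age is its own cohort (year - age fixed)
    vapply(age, function(a)
      forward_prevalence(sc$params, age_start = sc$onset_age,
                         p_start = sc$p_onset, grid = a, step = step,
                         year_start = year - (a - sc$onset_age))$p,
      numeric(1))
  }
}

#' Sample an observed prevalence cross-section
#'
#' Per age a, observed prevalence is `Binomial(n(a), p_true(year, a)) /
#' n(a)`.  Draws come from the current RNG stream; use
#' [simulate_inputs()] for the seeded, reproducible full set.
#'
#' @param sc an [idm_scenario()].
#' @param year one of the scenario's cross-section years `t0`, `t1`.
#' @return A [prevalence_cross_section()].
#' @export
sample_cross_section <- function(sc, year) {
  stopifnot(inherits(sc, "idm_scenario"))
  if (!year %in% c(sc$t0, sc$t1))
    stop("'year' must be one of the scenario cross-section years", call. = FALSE)
  p_true <- true_prevalence_surface(sc)(year, sc$ages)
  obs <- stats::rbinom(length(sc$ages), size = round(sc$n), prob = p_true) /
    round(sc$n)
  prevalence_cross_section(year, sc$ages, obs, n = sc$n)
}

#' Sample an observed incidence schedule at the midpoint year
#'
#' Events per age are `Poisson(i_true(a) * PY(a))`; the observed rate is
#' events / PY.
#'
#' @param sc an [idm_scenario()].
#' @return A [rate_schedule()] of kind `"incidence"`.
#' @export
sample_incidence <- function(sc) {
  stopifnot(inherits(sc, "idm_scenario"))
  i_true <- vapply(sc$ages, function(a)
    .eval_rate(sc$params$incidence, a, sc$t_mid), numeric(1))
  events <- stats::rpois(length(sc$ages), lambda = i_true * sc$py)
  rate_schedule(sc$t_mid, sc$ages, events / sc$py, py = sc$py,
                kind = "incidence")
}

#' Noise-free general-mortality schedule at the midpoint year
#'
#' `m(a) = p_true(a) * m1(a) + (1 - p_true(a)) * m0(a)`; emitted without
#' sampling noise because the analysis treats general mortality as fixed
#' external data.
#'
#' @param sc an [idm_scenario()].
#' @return A [rate_schedule()] of kind `"mortality"`.
#' @export
sample_mortality <- function(sc) {
  stopifnot(inherits(sc, "idm_scenario"))
  p_true <- true_prevalence_surface(sc)(sc$t_mid, sc$ages)
  m0 <- vapply(sc$ages, function(a)
    .eval_rate(sc$params$mortality_nondiseased, a, sc$t_mid), numeric(1))
  m1 <- vapply(sc$ages, function(a)
    .eval_rate(sc$params$mortality_diseased, a, sc$t_mid), numeric(1))
  rate_schedule(sc$t_mid, sc$ages, general_mortality(p_true, m0, m1),
                kind = "mortality")
}

#' Simulate the full, seeded input set of a scenario
#'
#' Sets the RNG to the scenario seed and draws, in fixed order, the two
#' prevalence cross-sections and the incidence schedule, plus the
#' noise-free mortality schedule.  Identical scenarios give identical
#' outputs.
#'
#' @param sc an [idm_scenario()].
#' @param seed optional seed override.
#' @return A list with elements `prev_t0`, `prev_t1`, `incidence`,
#'   `mortality`.
#' @export
simulate_inputs <- function(sc, seed = sc$seed) {
  stopifnot(inherits(sc, "idm_scenario"))
  set.seed(seed)
  list(prev_t0 = sample_cross_section(sc, sc$t0),
       prev_t1 = sample_cross_section(sc, sc$t1),
       incidence = sample_incidence(sc),
       mortality = sample_mortality(sc))
}

#' Bundled diabetes-like scenario
#'
#' A synthetic scenario emulating the shape of diabetes claims data for
#' men: prevalence below 0.005 until the mid-forties, rising to about a
#' quarter by age 90.  The true logit-prevalence follows a straight line in
#' age plus a young-age excess that decays over about seven years of age --
#' a stylised early-onset (type-1-like) plateau that flattens the local
#' logit slope below age 30.  The incidence and excess mortality rates are
#' derived from the illness-death identity, so the scenario is internally
#' consistent; the true mortality rate ratio declines from about 7 at age
#' 20 to about 1.3 at age 95.
#'
#' The young-age plateau is exactly the feature the transform-linear input
#' models cannot represent.  Combined with the tiny prevalence (1/p of
#' order 1000) it reproduces the instability of the inverse estimators at
#' young ages -- including negative estimated rate ratios -- while the
#' estimates above age 60 remain stable.
#'
#' @param seed scenario seed.
#' @param n per-age prevalence denominator (default 2e6, claims-data
#'   scale).
#' @param py per-age person-years for incidence (default 2e6).
#' @return An [idm_scenario()] on single-year ages 15-99, cross-sections
#'   2009 and 2015.
#' @export
scenario_diabetes_like <- function(seed = 1L, n = 2e6, py = 2e6) {
  b0 <- -9.46; b1 <- 0.093            # logit-prevalence trend line
  delta <- 0.45; tau <- 7             # young-age logit excess and decay
  ell  <- function(a) b0 + b1 * a + delta * exp(-(a - 15) / tau)
  ellp <- function(a) b1 - (delta / tau) * exp(-(a - 15) / tau)
  p_true <- function(a) .expit(ell(a))
  ## excess mortality declines with age (trend anchored to the logit line)
  dm <- function(a) pmax(0, exp(-11.8546 + 0.095 * a) / .expit(b0 + b1 * a) - b1)
  ## incidence from the illness-death identity: the true prevalence curve
  ## is the exact ODE solution by construction
  inc <- function(a) p_true(a) * (ellp(a) + dm(a))
  m0 <- function(a) 8e-4 * exp(0.088 * (a - 30))
  idm_scenario(
    idm_params(incidence = inc,
               mortality_nondiseased = m0,
               mortality_diseased = function(a) m0(a) + dm(a)),
    t0 = 2009, t1 = 2015, ages = 15:99, n = n, py = py,
    onset_age = 15, p_onset = p_true(15), seed = seed)
}

#' Bundled constant-ratio recovery scenario
#'
#' A well-behaved scenario for parameter-recovery studies: the mortality
#' rate ratio is exactly constant (`R = 2` by default) and both input
#' regression models are correctly specified by construction -- the true
#' logit-prevalence and the true log-incidence are exactly linear in age,
#' and the non-diseased mortality is derived from the illness-death
#' identity (it comes out Gompertz-like).  Prevalence rises from about
#' 0.015 at age 30 to about 0.15 at age 90.
#'
#' @param seed scenario seed.
#' @param R constant mortality rate ratio (the identity-based construction
#'   requires `R > 1`).
#' @param n,py per-age denominators and person-years (default 1e6).
#' @return An [idm_scenario()] on single-year ages 30-95, cross-sections
#'   2009 and 2015.
#' @export
scenario_constant_ratio <- function(seed = 1L, R = 2, n = 1e6, py = 1e6) {
  stopifnot(R > 1)
  b0 <- -5.45; b1 <- 0.0412           # true logit-prevalence line
  c0 <- -8.976; c1 <- 0.0519          # true log-incidence line
  p_line <- function(a) .expit(b0 + b1 * a)
  inc <- function(a) exp(c0 + c1 * a)
  ## identity: i = p*(b1 + dm); with dm = (R-1)*m0 this pins m0
  m0 <- function(a) pmax(1e-6, (inc(a) / p_line(a) - b1) / (R - 1))
  idm_scenario(
    idm_params(incidence = inc,
               mortality_nondiseased = m0,
               mortality_diseased = function(a) R * m0(a)),
    t0 = 2009, t1 = 2015, ages = 30:95, n = n, py = py,
    onset_age = 30, p_onset = p_line(30), seed = seed)
}
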