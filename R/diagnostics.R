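#' Instability diagnostics
#'
#' The inverse estimators are exact with exact inputs but numerically
#' fragile where the prevalence is small (the factor 1/p amplifies any
#' input error) or where the rate-ratio denominator `(1-p)*(m-i) + dp`
#' comes close to zero (the regime where the incidence approaches the
#' general mortality and the prevalence derivative is small).  These
#' diagnostics classify estimates without ever altering them: implausible
#' values -- including negative rate ratios, which a ratio of positive
#' rates cannot take -- are reported verbatim and flagged.
#'
#' @name diagnostics
NULL

#' Default instability thresholds
#'
#' `small_prevalence`: flag when `1/p` exceeds `inv_p_threshold`
#' (default 100, i.e. p < 0.01).  `near_singular_denominator`: flag when
#' `|(1-p)*(m-i) + dp| < epsilon_denominator * max(i, m)` (default 0.05).
#' `implausible_magnitude`: flag when `|R| > ratio_ceiling` (default 50;
#' the ceiling is this package's own convention -- the literature gives no
#' numeric cutoff beyond the sign).
#'
#' @param inv_p_threshold small-prevalence cutoff on 1/p.
#' @param epsilon_denominator relative near-zero margin for the rate-ratio
#'   denominator.
#' @param ratio_ceiling plausibility ceiling on |R|.
#' @return A list of thresholds for [flag_estimate()].
#' @export
instability_thresholds <- function(inv_p_threshold = 100,
                                   epsilon_denominator = 0.05,
                                   ratio_ceiling = 50) {
  stopifnot(inv_p_threshold > 0, epsilon_denominator > 0, ratio_ceiling > 0)
  list(inv_p_threshold = inv_p_threshold,
       epsilon_denominator = epsilon_denominator,
       ratio_ceiling = ratio_ceiling)
}

#' Flag unstable excess-mortality estimates
#'
#' Pure classification of estimator inputs and outputs; values are never
#' modified.  Vectorised over all arguments.
#'
#' @param p prevalence used in the estimators.
#' @param dp cohort-direction prevalence derivative.
#' @param i incidence rate.
#' @param m general mortality rate.
#' @param rate_ratio the estimated mortality rate ratio.
#' @param thresholds see [instability_thresholds()].
#' @return A data.frame of logicals with columns `small_prevalence`,
#'   `near_singular_denominator`, `negative_ratio`,
#'   `implausible_magnitude`, and `any` (their union).
#' @export
flag_estimate <- function(p, dp, i, m, rate_ratio,
                          thresholds = instability_thresholds()) {
  denom <- (1 - p) * (m - i) + dp
  out <- data.frame(
    small_prevalence = 1 / p > thresholds$inv_p_threshold,
    near_singular_denominator =
      abs(denom) < thresholds$epsilon_denominator * pmax(i, m),
    negative_ratio = rate_ratio < 0,
    implausible_magnitude = abs(rate_ratio) > thresholds$ratio_ceiling)
  out$any <- out$small_prevalence | out$near_singular_denominator |
    out$negative_ratio | out$implausible_magnitude
  out
}

#' Check the analytic bound chain R >= 1 + dm/m >= dm/m
#'
#' For genuine rates the ratio and the difference estimate are ordered:
#' since `m = p*m1 + (1-p)*m0 >= m0`, it holds `dm/m <= dm/m0 = R - 1`,
#' hence `R >= 1 + dm/m >= dm/m`.  The chain is only meaningful when the
#' implied non-diseased mortality `m0 = m / (1 + p*(R-1))` is positive and
#' the excess mortality estimate is nonnegative; outside that precondition
#' the result is `NA` (not applicable), distinct from `FALSE`.
#'
#' @param rate_ratio estimated mortality rate ratio R.
#' @param delta_m estimated excess mortality rate.
#' @param p prevalence used in the estimators.
#' @param m general mortality rate.
#' @param tol relative tolerance on the inequalities.
#' @return Logical (`TRUE`/`FALSE`/`NA`), vectorised.
#' @export
check_bound_chain <- function(rate_ratio, delta_m, p, m, tol = 1e-10) {
  one_plus <- 1 + p * (rate_ratio - 1)
  implied_m0 <- ifelse(one_plus > 0 & m > 0, m / one_plus, NA_real_)
  applicable <- !is.na(implied_m0) & implied_m0 > 0 & delta_m >= 0
  slack <- tol * pmax(1, abs(rate_ratio), abs(delta_m / m))
  ok <- rate_ratio >= 1 + delta_m / m - slack &
    1 + delta_m / m >= delta_m / m - slack
  ifelse(applicable, ok, NA)
}
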