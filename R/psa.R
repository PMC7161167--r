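#' Probabilistic sensitivity analysis
#'
#' Propagates input uncertainty through the excess-mortality estimators.
#' The sampled inputs are the coefficient pairs of the three fitted
#' transform-linear models (prevalence at the two cross-section years and
#' incidence at the midpoint year); each pair is drawn from its bivariate
#' normal asymptotic OLS distribution, independently across models.  The
#' general mortality schedule is treated as fixed external data.  Outcomes
#' (excess mortality rate, its ratio to the general mortality, and the
#' mortality rate ratio) are summarised per age by the empirical median
#' and a quantile interval.
#'
#' @name psa
NULL

#' PSA configuration
#'
#' @param ages evaluation age grid (years), strictly increasing.
#' @param n_draws number of Monte-Carlo draws (default 5000).
#' @param seed RNG seed.
#' @param quantiles lower/upper empirical quantiles of the reported
#'   interval (default 2.5% and 97.5%, an approximate 95% interval).
#' @param thresholds instability thresholds, see
#'   [instability_thresholds()].
#' @param keep_draws retain the per-draw outcome matrices in the result
#'   (needed by [aggregate_age_groups()]; default TRUE).
#' @return A list of class `psa_config`.
#' @export
psa_config <- function(ages, n_draws = 5000, seed = 1L,
                       quantiles = c(0.025, 0.975),
                       thresholds = instability_thresholds(),
                       keep_draws = TRUE) {
  ages <- as.numeric(ages)
  if (is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly increasing", call. = FALSE)
  if (n_draws < 1) stop("'n_draws' must be >= 1", call. = FALSE)
  if (!(quantiles[1] > 0 && quantiles[1] < 0.5 &&
        quantiles[2] > 0.5 && quantiles[2] < 1))
    stop("quantiles must satisfy 0 < lo < 0.5 < hi < 1", call. = FALSE)
  structure(list(ages = ages, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), quantiles = quantiles,
                 thresholds = thresholds, keep_draws = isTRUE(keep_draws)),
            class = "psa_config")
}

## one multivariate-normal coefficient draw for a fitted model
.draw_coefficients <- function(model, scale = 1) {
  sigma <- model$coef_covariance * scale
  if (all(sigma == 0)) return(c(model$intercept, model$slope))
  draw <- tryCatch(
    MASS::mvrnorm(1, mu = c(model$intercept, model$slope), Sigma = sigma),
    error = function(e) stop("coefficient covariance is not positive ",
                             "semi-definite: ", conditionMessage(e),
                             call. = FALSE))
  as.numeric(draw)
}

#' Draw one joint sample of the three input models
#'
#' Each model's (intercept, slope) pair is sampled from its bivariate
#' normal OLS distribution; the three models are independent.  Consumes
#' the current RNG stream ([run_psa()] seeds it).
#'
#' @param prev_t0,prev_t1 fitted logit prevalence models.
#' @param inc fitted log incidence model.
#' @param covariance_scale multiplier on all coefficient covariances
#'   (1 = the fitted uncertainty).
#' @return A list of the three models with coefficients replaced by the
#'   draw (covariances zeroed: a draw is a point).
#' @export
sample_input_models <- function(prev_t0, prev_t1, inc, covariance_scale = 1) {
  zero <- matrix(0, 2, 2)
  draw1 <- .draw_coefficients(prev_t0, covariance_scale)
  draw2 <- .draw_coefficients(prev_t1, covariance_scale)
  draw3 <- .draw_coefficients(inc, covariance_scale)
  repl <- function(m, d) {
    m$intercept <- d[1]; m$slope <- d[2]; m$coef_covariance <- zero; m
  }
  list(prev_t0 = repl(prev_t0, draw1), prev_t1 = repl(prev_t1, draw2),
       inc = repl(inc, draw3))
}

## rate-ratio estimate that returns NaN (instead of an error) on an
## exactly zero denominator, for use inside the Monte-Carlo loop
.rate_ratio_or_nan <- function(p, dp, i, m) {
  denom <- (1 - p) * (m - i) + dp
  out <- 1 + (1 / p) * (i * (1 - p) - dp) / denom
  out[denom == 0] <- NaN
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw the prevalence, its cohort derivative and the incidence
#' are rebuilt at every evaluation age from the sampled coefficients, the
#' estimators are applied, and instability flags are recorded.  Summaries
#' are empirical quantiles over the finite draws; draws yielding
#' non-finite outcomes at an age are counted (column `n_nonfinite`) and
#' excluded from that age's quantiles.  If every draw is non-finite at an
#' age the summary there is `NaN`, not an error.
#'
#' @param prev_t0,prev_t1 fitted logit prevalence models (with `year`
#'   fields `t1 > t0`).
#' @param inc fitted log incidence model.
#' @param mort a [rate_schedule()] of general mortality covering the
#'   evaluation ages (treated as fixed).
#' @param cfg a [psa_config()].
#' @param covariance_scale multiplier on input covariances (for
#'   sensitivity-of-the-sensitivity checks).
#' @return A `psa_result`: list with `summary` (data.frame: age, outcome,
#'   median, lo, hi), `flag_counts` (per age), `draws` (per-outcome
#'   matrices, if kept), `n_draws`, `seed`, `quantiles`, `ages`.
#' @export
run_psa <- function(prev_t0, prev_t1, inc, mort, cfg, covariance_scale = 1) {
  stopifnot(inherits(cfg, "psa_config"))
  ages <- cfg$ages
  m_fixed <- mortality_at(mort, ages)
  n_ages <- length(ages)
  dm_draws <- rr_draws <- matrix(NA_real_, cfg$n_draws, n_ages)
  flag_mat <- matrix(0L, n_ages, 5L)
  colnames(flag_mat) <- c("small_prevalence", "near_singular_denominator",
                          "negative_ratio", "implausible_magnitude", "any")

  set.seed(cfg$seed)
  for (k in seq_len(cfg$n_draws)) {
    dr <- sample_input_models(prev_t0, prev_t1, inc, covariance_scale)
    cd <- cohort_derivative(dr$prev_t0, dr$prev_t1, ages)
    i_k <- predict(dr$inc, ages)
    dm_draws[k, ] <- (i_k - cd$dp / (1 - cd$p)) / cd$p
    rr_draws[k, ] <- .rate_ratio_or_nan(cd$p, cd$dp, i_k, m_fixed)
    fl <- flag_estimate(cd$p, cd$dp, i_k, m_fixed, rr_draws[k, ],
                        cfg$thresholds)
    flag_mat <- flag_mat + matrix(as.integer(as.matrix(fl)), nrow = n_ages)
  }
  ratio_draws <- sweep(dm_draws, 2, m_fixed, "/")

  summarise <- function(draws, outcome) {
    t(vapply(seq_len(n_ages), function(j) {
      x <- draws[, j]; x <- x[is.finite(x)]
      if (!length(x)) return(c(NaN, NaN, NaN))
      c(stats::median(x), stats::quantile(x, cfg$quantiles, names = FALSE))
    }, numeric(3)))
  }
  smry <- do.call(rbind, lapply(
    list(delta_m = dm_draws, dm_over_m = ratio_draws, rate_ratio = rr_draws),
    summarise))
  summary <- data.frame(
    age = rep(ages, 3L),
    outcome = rep(c("delta_m", "dm_over_m", "rate_ratio"), each = n_ages),
    median = smry[, 1], lo = smry[, 2], hi = smry[, 3])
  flag_counts <- data.frame(age = ages, flag_mat,
                            n_nonfinite = colSums(!is.finite(rr_draws)))
  structure(list(summary = summary, flag_counts = flag_counts,
                 draws = if (cfg$keep_draws)
                   list(delta_m = dm_draws, dm_over_m = ratio_draws,
                        rate_ratio = rr_draws),
                 n_draws = cfg$n_draws, seed = cfg$seed,
                 quantiles = cfg$quantiles, ages = ages),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA result: %d draws, seed %d, %d evaluation ages\n",
              x$n_draws, x$seed, length(x$ages)))
  rr <- x$summary[x$summary$outcome == "rate_ratio", ]
  print(utils::head(rr, 10), row.names = FALSE)
  if (nrow(rr) > 10) cat("...\n")
  invisible(x)
}

#' Aggregate a PSA result into age groups
#'
#' Each group is represented by its midpoint age (an open-ended last group
#' by `open_group_age`, default 92.5); the group's per-draw outcome is the
#' outcome evaluated at that representative age, so group summaries equal
#' the representative age's summaries.  The representative age must be on
#' the evaluation grid of the PSA run.
#'
#' @param res a `psa_result` run with `keep_draws = TRUE`.
#' @param groups data.frame with columns `lo`, `hi` (closed age intervals,
#'   non-overlapping; `hi = Inf` for the open-ended last group) and
#'   optionally `label`.
#' @param open_group_age representative age of an open-ended group.
#' @return A data.frame: one row per group and outcome with `label`,
#'   `representative_age`, `median`, `lo`, `hi`, flag counts.
#' @export
aggregate_age_groups <- function(res, groups, open_group_age = 92.5) {
  stopifnot(inherits(res, "psa_result"))
  if (is.null(res$draws))
    stop("PSA result was run with keep_draws = FALSE", call. = FALSE)
  groups <- as.data.frame(groups)
  if (!all(c("lo", "hi") %in% names(groups)))
    stop("'groups' needs columns 'lo' and 'hi'", call. = FALSE)
  if (nrow(groups) == 0) stop("empty group set", call. = FALSE)
  ord <- order(groups$lo)
  groups <- groups[ord, , drop = FALSE]
  if (any(groups$lo[-1] <= groups$hi[-nrow(groups)]))
    stop("age groups must be non-overlapping", call. = FALSE)
  if (is.null(groups$label))
    groups$label <- ifelse(is.finite(groups$hi),
                           paste0(groups$lo, "-", groups$hi),
                           paste0(groups$lo, "+"))
  rep_age <- ifelse(is.finite(groups$hi), (groups$lo + groups$hi) / 2,
                    open_group_age)
  out <- list()
  for (g in seq_len(nrow(groups))) {
    j <- which(abs(res$ages - rep_age[g]) < 1e-8)
    if (!length(j))
      stop(sprintf("representative age %g of group '%s' is not on the PSA grid",
                   rep_age[g], groups$label[g]), call. = FALSE)
    for (oc in names(res$draws)) {
      x <- res$draws[[oc]][, j]; xf <- x[is.finite(x)]
      s <- if (length(xf))
        c(stats::median(xf), stats::quantile(xf, res$quantiles, names = FALSE))
      else c(NaN, NaN, NaN)
      out[[length(out) + 1L]] <- data.frame(
        label = groups$label[g], representative_age = rep_age[g],
        outcome = oc, median = s[1], lo = s[2], hi = s[3],
        n_flagged = res$flag_counts$any[j],
        n_nonfinite = res$flag_counts$n_nonfinite[j])
    }
  }
  do.call(rbind, out)
}
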