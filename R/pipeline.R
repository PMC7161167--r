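#' File formats, configuration and the analysis pipeline
#'
#' The pipeline ties the stages together: read the four input CSVs (two
#' prevalence cross-sections, incidence and general mortality at the
#' midpoint year), fit the transform-linear input models, form the cohort
#' derivative, run the probabilistic sensitivity analysis, aggregate into
#' age groups, attach instability flags, and serialise the results
#' together with a reproducibility manifest.
#'
#' The single input dialect is a headed CSV with columns `age` (single
#' years, integer or decimal), `value` (a proportion for prevalence, a
#' rate per person-year otherwise) and optionally `n` (prevalence
#' denominators) or `py` (person-years).  Grouped sources must be
#' pre-expanded to single years.
#'
#' @name pipeline
NULL

#' Read an age-specific schedule from CSV
#'
#' @param path CSV file with columns `age`, `value`, optional `n` or `py`.
#' @param kind `"prevalence"`, `"incidence"` or `"mortality"`; controls
#'   range checks and the returned class.
#' @param year calendar year to attach to the returned object.
#' @param per_100k if TRUE, `value` is divided by 1e5 on read (for rate
#'   tables published per 100 000 person-years); logged loudly.
#' @return A [prevalence_cross_section()] for `kind = "prevalence"`,
#'   otherwise a [rate_schedule()].
#' @export
read_rate_csv <- function(path, kind = c("prevalence", "incidence",
                                         "mortality"),
                          year = NA, per_100k = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("age", "value")) {
    if (!col %in% names(d))
      stop(sprintf("%s: missing required column '%s'", path, col),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) | is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric or missing '%s' at row %d", path, col,
                   bad[1]), call. = FALSE)
    d[[col]] <- v
  }
  if (per_100k) {
    message("read_rate_csv: interpreting '", path,
            "' as per 100,000 person-years; dividing values by 1e5")
    d$value <- d$value / 1e5
  }
  dup <- which(duplicated(d$age))
  if (length(dup))
    stop(sprintf("%s: duplicate age %g at row %d", path, d$age[dup[1]],
                 dup[1]), call. = FALSE)
  rng <- switch(kind, prevalence = c(0, 1), c(0, Inf))
  bad <- which(d$value < rng[1] | d$value > rng[2])
  if (length(bad))
    stop(sprintf("%s: column 'value' out of range for %s at row %d (%g)",
                 path, kind, bad[1], d$value[bad[1]]), call. = FALSE)
  if (kind == "prevalence")
    prevalence_cross_section(year, d$age, d$value, n = d$n)
  else
    rate_schedule(year, d$age, d$value, py = d$py, kind = kind)
}

#' Write an age-specific schedule to CSV
#'
#' Inverse of [read_rate_csv()]: round-tripping is the identity.
#'
#' @param x a [prevalence_cross_section()] or [rate_schedule()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_csv <- function(x, path) {
  if (inherits(x, "prevalence_cross_section")) {
    d <- data.frame(age = x$age, value = x$p)
    if (!is.null(x$n)) d$n <- x$n
  } else if (inherits(x, "rate_schedule")) {
    d <- data.frame(age = x$age, value = x$rate)
    if (!is.null(x$py)) d$py <- x$py
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario's simulated inputs as pipeline-ready CSVs
#'
#' Simulates the seeded input set of a scenario and writes the four CSVs
#' the pipeline reads, so synthetic and real runs are interchangeable.
#'
#' @param sc an [idm_scenario()].
#' @param dir output directory (created if missing).
#' @param seed optional seed override.
#' @return Named character vector of the four file paths.
#' @export
simulate_scenario_csv <- function(sc, dir, seed = sc$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ins <- simulate_inputs(sc, seed)
  paths <- c(prevalence_t0 = file.path(dir, sprintf("prevalence_%d.csv", sc$t0)),
             prevalence_t1 = file.path(dir, sprintf("prevalence_%d.csv", sc$t1)),
             incidence = file.path(dir, "incidence.csv"),
             mortality = file.path(dir, "mortality.csv"))
  write_rate_csv(ins$prev_t0, paths[["prevalence_t0"]])
  write_rate_csv(ins$prev_t1, paths[["prevalence_t1"]])
  write_rate_csv(ins$incidence, paths[["incidence"]])
  write_rate_csv(ins$mortality, paths[["mortality"]])
  paths
}

#' Default age grouping (five-year groups plus an open-ended last group)
#'
#' @param lo,hi closed range covered by five-year groups.
#' @param open_from lower bound of the open-ended last group.
#' @return data.frame with columns `lo`, `hi`.
#' @export
default_age_groups <- function(lo = 15, hi = 89, open_from = 90) {
  starts <- seq(lo, hi, by = 5)
  rbind(data.frame(lo = starts, hi = starts + 4),
        data.frame(lo = open_from, hi = Inf))
}

#' Build and validate a pipeline configuration
#'
#' @param x either a path to a YAML file or a named list with entries
#'   `inputs` (paths `prevalence_t0`, `prevalence_t1`, `incidence`,
#'   `mortality`), `years` (`t0`, `t1`), and optionally `ages`
#'   (`min`, `max`, `step`), `age_groups` (list of `lo`/`hi` pairs, `hi`
#'   omitted for the open-ended group), `fit_age_range`, `psa`
#'   (`n_draws`, `seed`, `quantiles`), `thresholds`, `per_100k`,
#'   `open_group_age`, `output_dir`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    yaml::read_yaml(x)
  } else if (is.list(x)) x else
    stop("'x' must be a YAML path or a list", call. = FALSE)

  for (f in c("inputs", "years"))
    if (is.null(cfg[[f]])) stop("config: missing '", f, "'", call. = FALSE)
  for (f in c("prevalence_t0", "prevalence_t1", "incidence", "mortality")) {
    p <- cfg$inputs[[f]]
    if (is.null(p)) stop("config: missing inputs$", f, call. = FALSE)
    if (!file.exists(p))
      stop("config: inputs$", f, " does not exist: ", p, call. = FALSE)
  }
  if (is.null(cfg$years$t0) || is.null(cfg$years$t1) ||
      cfg$years$t1 <= cfg$years$t0)
    stop("config: years must satisfy t1 > t0", call. = FALSE)

  ages <- cfg$ages
  cfg$ages <- list(min = ages$min %||% 17, max = ages$max %||% 95,
                   step = ages$step %||% 1)
  if (cfg$ages$step <= 0 || cfg$ages$max <= cfg$ages$min)
    stop("config: invalid evaluation age range", call. = FALSE)
  cfg$age_groups <- if (is.null(cfg$age_groups)) default_age_groups() else {
    do.call(rbind, lapply(cfg$age_groups, function(g)
      data.frame(lo = g$lo, hi = g$hi %||% Inf)))
  }
  cfg$fit_age_range <- cfg$fit_age_range %||% c(15, 100)
  psa <- cfg$psa
  cfg$psa <- list(n_draws = psa$n_draws %||% 5000L,
                  seed = psa$seed %||% 1L,
                  quantiles = psa$quantiles %||% c(0.025, 0.975))
  th <- cfg$thresholds
  cfg$thresholds <- instability_thresholds(
    inv_p_threshold = th$inv_p_threshold %||% 100,
    epsilon_denominator = th$epsilon_denominator %||% 0.05,
    ratio_ceiling = th$ratio_ceiling %||% 50)
  cfg$per_100k <- isTRUE(cfg$per_100k)
  cfg$open_group_age <- cfg$open_group_age %||% 92.5
  cfg$output_dir <- cfg$output_dir %||% "idmexcess-output"
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single point-estimate pass (no Monte-Carlo)
#'
#' Applies both estimators at the requested ages using the fitted models'
#' point estimates, with instability flags attached.
#'
#' @param prev_t0,prev_t1 fitted logit prevalence models.
#' @param inc fitted log incidence model.
#' @param mort general-mortality [rate_schedule()].
#' @param ages evaluation ages.
#' @param thresholds see [instability_thresholds()].
#' @return data.frame: age, p, dp, i, m, delta_m, rate_ratio, dm_over_m,
#'   and the flag columns of [flag_estimate()].
#' @export
estimate_point <- function(prev_t0, prev_t1, inc, mort, ages,
                           thresholds = instability_thresholds()) {
  cd <- cohort_derivative(prev_t0, prev_t1, ages)
  i <- predict(inc, ages)
  m <- mortality_at(mort, ages)
  delta_m <- estimate_delta_m(cd$p, cd$dp, i)
  rate_ratio <- .rate_ratio_or_nan(cd$p, cd$dp, i, m)
  fl <- flag_estimate(cd$p, cd$dp, i, m, rate_ratio, thresholds)
  cbind(data.frame(age = ages, p = cd$p, dp = cd$dp, i = i, m = m,
                   delta_m = delta_m, rate_ratio = rate_ratio,
                   dm_over_m = delta_m / m), fl)
}

#' Run the full excess-mortality pipeline
#'
#' Stages: read inputs, fit the input models, run the PSA over the
#' evaluation age grid (always including the group representative ages),
#' aggregate into age groups, and compute the point-estimate pass.  With
#' `write = TRUE` the results are serialised to `output_dir`: an
#' age-group table (`age_group_table.csv`: group, median/interval of the
#' rate ratio and of delta_m/m, flag counts), an age-resolved table
#' (`dm_over_m_by_age.csv`), and a JSON run manifest (seed, draws, config
#' hash, package version).  Outputs are written only after every stage
#' has succeeded, so a failed run leaves no partial files.
#'
#' @param cfg a [pipeline_config()] (or something accepted by it).
#' @param write write output files (default TRUE).
#' @param quiet suppress per-stage messages.
#' @return List with `psa` (the `psa_result`), `groups` (grouped
#'   summaries), `point` (point-estimate table), `paths` (written files,
#'   if any).
#' @export
run_pipeline <- function(cfg, write = TRUE, quiet = FALSE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  say <- function(...) if (!quiet) message("[idmexcess] ", ...)

  say("stage 1/5: reading inputs")
  prev0 <- read_rate_csv(cfg$inputs$prevalence_t0, "prevalence",
                         year = cfg$years$t0, per_100k = FALSE)
  prev1 <- read_rate_csv(cfg$inputs$prevalence_t1, "prevalence",
                         year = cfg$years$t1, per_100k = FALSE)
  inc_s <- read_rate_csv(cfg$inputs$incidence, "incidence",
                         year = (cfg$years$t0 + cfg$years$t1) / 2,
                         per_100k = cfg$per_100k)
  mort <- read_rate_csv(cfg$inputs$mortality, "mortality",
                        year = (cfg$years$t0 + cfg$years$t1) / 2,
                        per_100k = cfg$per_100k)

  say("stage 2/5: fitting input models")
  f0 <- fit_logit_linear_prevalence(prev0, age_range = cfg$fit_age_range)
  f1 <- fit_logit_linear_prevalence(prev1, age_range = cfg$fit_age_range)
  fi <- fit_log_linear_incidence(inc_s, age_range = cfg$fit_age_range)

  rep_ages <- ifelse(is.finite(cfg$age_groups$hi),
                     (cfg$age_groups$lo + cfg$age_groups$hi) / 2,
                     cfg$open_group_age)
  eval_ages <- sort(unique(c(
    seq(cfg$ages$min, cfg$ages$max, by = cfg$ages$step), rep_ages)))
  span <- range(mort$age)
  eval_ages <- eval_ages[eval_ages >= span[1] & eval_ages <= span[2]]

  say("stage 3/5: probabilistic sensitivity analysis (",
      cfg$psa$n_draws, " draws, seed ", cfg$psa$seed, ")")
  pcfg <- psa_config(eval_ages, n_draws = cfg$psa$n_draws,
                     seed = cfg$psa$seed, quantiles = cfg$psa$quantiles,
                     thresholds = cfg$thresholds)
  psa <- run_psa(f0, f1, fi, mort, pcfg)

  say("stage 4/5: age-group aggregation")
  groups <- aggregate_age_groups(psa, cfg$age_groups,
                                 open_group_age = cfg$open_group_age)

  say("stage 5/5: point-estimate pass")
  point <- estimate_point(f0, f1, fi, mort, eval_ages, cfg$thresholds)

  paths <- NULL
  if (write) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(groups = file.path(cfg$output_dir, "age_group_table.csv"),
               by_age = file.path(cfg$output_dir, "dm_over_m_by_age.csv"),
               manifest = file.path(cfg$output_dir, "manifest.json"))
    gr <- groups[groups$outcome %in% c("rate_ratio", "dm_over_m"), ]
    utils::write.csv(format(gr, digits = 10, trim = TRUE, scientific = FALSE),
                     paths[["groups"]], row.names = FALSE, quote = FALSE)
    by_age <- psa$summary[psa$summary$outcome == "dm_over_m", ]
    by_age <- merge(by_age,
                    psa$flag_counts[, c("age", "any", "n_nonfinite")],
                    by = "age")
    utils::write.csv(format(by_age, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     paths[["by_age"]], row.names = FALSE, quote = FALSE)
    manifest <- list(
      package = "idmexcess",
      version = tryCatch(as.character(utils::packageVersion("idmexcess")),
                         error = function(e) "dev"),
      seed = cfg$psa$seed, n_draws = cfg$psa$n_draws,
      quantiles = cfg$psa$quantiles,
      evaluation_ages = range(eval_ages),
      config_hash = .config_hash(cfg))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    say("outputs written to ", cfg$output_dir)
  }
  list(psa = psa, groups = groups, point = point, paths = paths)
}

## md5 of the canonical JSON serialisation of the config
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
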