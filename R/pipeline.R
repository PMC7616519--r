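## Configuration-driven orchestration: simulate/ingest -> exposure ->
## population -> strata -> fits -> comparison, with a provenance manifest.

#' Default pipeline configuration
#'
#' A fully synthetic run: two warm seasons over 12 counties, baseline
#' thresholds from the 12 preceding years, all-cause encounters of both
#' types, standardized insured counts.
#'
#' @param seed integer root seed.
#' @return a config list; see [validate_config()] for the schema.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    synthetic = list(n_counties = 12L, years = c(2018L, 2019L)),
    exposure = list(quantile = 97.5, min_run = 2L, variant = "hw_any"),
    model = list(cause = "all", encounter_type = c("ED", "inpatient"),
                 standardized = TRUE, warm_season = TRUE),
    output_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks field types and cross-field constraints, distinguishing fatal
#' errors from warnings.
#'
#' @param config a config list (e.g. from [default_config()] or
#'   [read_config()]).
#' @return list with `errors` and `warnings` (character vectors); an empty
#'   `errors` vector means the config is runnable.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp)
    errors <- c(errors, "exactly one of 'synthetic' or 'inputs' must be given")
  q <- config$exposure$quantile %||% 97.5
  if (!is.numeric(q) || q <= 0 || q >= 100)
    errors <- c(errors, "exposure.quantile must be in (0, 100)")
  mr <- config$exposure$min_run %||% 2L
  if (!is.numeric(mr) || mr < 1)
    errors <- c(errors, "exposure.min_run must be >= 1")
  va <- config$exposure$variant %||% "hw_any"
  if (!va %in% c("hw_any", "exceed_simple", "hw_split"))
    errors <- c(errors, sprintf("unknown exposure.variant '%s'", va))
  if (is.null(config$seed) || !is.numeric(config$seed))
    errors <- c(errors, "seed must be an integer")
  if (has_inp) {
    for (f in c("climate_csv", "counts_ref_csv", "counts_ins_csv",
                "population_csv", "enrollment_csv")) {
      p <- config$inputs[[f]]
      if (is.null(p)) errors <- c(errors, sprintf("inputs.%s is required", f))
      else if (!file.exists(p))
        errors <- c(errors, sprintf("inputs.%s: file not found: %s", f, p))
    }
    by <- config$inputs$baseline_years
    if (is.null(by))
      errors <- c(errors, "inputs.baseline_years is required")
  }
  if (has_syn) {
    yrs <- config$synthetic$years
    if (is.null(yrs) || !is.numeric(yrs))
      errors <- c(errors, "synthetic.years must be numeric years")
    nby <- config$synthetic$baseline_years
    if (!is.null(nby) && !is.null(yrs) && max(nby) >= min(yrs))
      warnings <- c(warnings, "baseline years overlap the study years")
  }
  list(errors = errors, warnings = warnings)
}

#' Read a YAML pipeline configuration
#' @param path YAML file path.
#' @return config list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable config file: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  if (!is.null(cfg$synthetic) || !is.null(cfg$inputs)) base$synthetic <- NULL
  utils::modifyList(base, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest CSVs) -> heatwave exposure -> person-time,
#' standardization, incidence rates -> case-crossover strata -> per-dataset
#' fits -> combined rIRR. Writes CSV/JSON artifacts when `output_dir` is
#' set and always returns the result bundle with a provenance manifest
#' (config hash, seed, package version, row counts, dropped-stratum tally).
#'
#' @param config a config list; validated before running.
#' @return list: `rates`, `weights`, `fit_ref`, `fit_ins`, `comparison`
#'   (an `rirr_result`), `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  v <- validate_config(config)
  for (w in v$warnings) warning(w, call. = FALSE)
  if (length(v$errors))
    stop(paste(c("invalid config:", v$errors), collapse = "\n  "))
  seed <- as.integer(config$seed)
  counts_rows <- function(x) if (is.null(x)) 0L else nrow(x)

  stage <- "ingest"
  out <- tryCatch({
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      sim <- simulate_study(
        n_counties = syn$n_counties %||% 12L,
        years = as.integer(syn$years),
        baseline_years = syn$baseline_years,
        climate = do.call(climate_params, syn$climate %||% list()),
        effects = do.call(effect_params, syn$effects %||% list()),
        coverage = do.call(coverage_params, syn$coverage %||% list()),
        seed = seed)
      climate <- sim$climate; cal <- sim$calendar; thr <- sim$thresholds
      pop <- sim$population; enr <- sim$enrollment
      counts_ref <- sim$counts_ref; counts_ins <- sim$counts_ins
      pt_ref <- sim$person_time_ref; pt_ins <- sim$person_time_ins
      holidays <- sim$holidays
      years <- sim$years
    } else {
      inp <- config$inputs
      climate <- read.csv(inp$climate_csv, stringsAsFactors = FALSE)
      counts_ref <- read.csv(inp$counts_ref_csv, stringsAsFactors = FALSE)
      counts_ins <- read.csv(inp$counts_ins_csv, stringsAsFactors = FALSE)
      pop <- read.csv(inp$population_csv, stringsAsFactors = FALSE)
      enr <- read.csv(inp$enrollment_csv, stringsAsFactors = FALSE)
      years <- sort(unique(as.integer(format(as.Date(counts_ref$date), "%Y"))))
      holidays <- if (!is.null(config$holidays)) as.Date(unlist(config$holidays))
                  else default_holidays(years)
      stage <- "exposure"
      thr <- baseline_percentile(climate, as.integer(inp$baseline_years),
                                 q = config$exposure$quantile %||% 97.5)
      study_clim <- climate[as.integer(format(as.Date(climate$date), "%Y"))
                            %in% years, ]
      cal <- detect_heatwaves(study_clim, thr,
                              min_run = config$exposure$min_run %||% 2L)
      climate <- study_clim
      stage <- "population"
      dates <- sort(unique(as.Date(climate$date)))
      dates <- dates[in_warm_season(dates)]
      pt_ref <- person_time_from_population(pop, dates)
      pt_ins <- person_time_from_enrollment(enr, dates)
    }

    stage <- "population"
    enr_annual <- group_sum(enr, c("county", "age_group", "sex", "year"),
                            "count")
    enr_annual$count <- as.numeric(enr_annual$count) / 12  # monthly average
    enr_annual$year <- as.integer(enr_annual$year)
    wts <- standardization_weights(enr_annual, pop)
    mdl <- config$model %||% list()
    sel <- function(x) {
      if (!is.null(mdl$cause)) x <- x[x$cause %in% mdl$cause, , drop = FALSE]
      if (!is.null(mdl$encounter_type))
        x <- x[x$encounter_type %in% mdl$encounter_type, , drop = FALSE]
      x
    }
    counts_ins_model <- if (isTRUE(mdl$standardized))
      standardize_counts(counts_ins, wts) else counts_ins
    rates <- rbind(
      cbind(dataset = "reference",
            incidence_rate(counts_ref, pt_ref)),
      cbind(dataset = "insured_crude",
            incidence_rate(counts_ins, pt_ins)),
      cbind(dataset = "insured_standardized",
            incidence_rate(standardize_counts(counts_ins, wts), pt_ins)))

    stage <- "strata"
    variant <- config$exposure$variant %||% "hw_any"
    strata_ref <- build_strata(sel(counts_ref), cal, climate,
                               holidays = holidays, exposure = variant,
                               warm_season = isTRUE(mdl$warm_season %||% TRUE))
    strata_ins <- build_strata(sel(counts_ins_model), cal, climate,
                               holidays = holidays, exposure = variant,
                               warm_season = isTRUE(mdl$warm_season %||% TRUE))

    stage <- "fit"
    expo_col <- if (variant == "hw_split") "hw_later" else "hw"
    cmp <- fit_rirr(strata_ref, strata_ins, exposure_column = expo_col)

    manifest <- list(
      package_version = as.character(utils::packageVersion("heatcc")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      config_hash = config_hash(config),
      exposure = list(variant = variant,
                      quantile = config$exposure$quantile %||% 97.5,
                      min_run = config$exposure$min_run %||% 2L),
      rows = list(climate = counts_rows(climate),
                  counts_reference = counts_rows(counts_ref),
                  counts_insured = counts_rows(counts_ins),
                  population = counts_rows(pop), enrollment = counts_rows(enr)),
      strata = list(reference = length(strata_ref),
                    insured = length(strata_ins),
                    dropped_reference = attr(strata_ref, "dropped_strata"),
                    dropped_insured = attr(strata_ins, "dropped_strata")))

    list(rates = rates, weights = wts, thresholds = thr, calendar = cal,
         fit_ref = cmp$fit_ref, fit_ins = cmp$fit_ins, comparison = cmp,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

## stable hash of the config (order-insensitive within lists)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 97 + 1))
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$rates, file.path(dir, "rates.csv"), row.names = FALSE)
  write.csv(result$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  write.csv(result$thresholds, file.path(dir, "thresholds.csv"),
            row.names = FALSE)
  write.csv(result$calendar, file.path(dir, "calendar.csv"), row.names = FALSE)
  cmp <- result$comparison
  fit_json <- function(f) list(
    beta = as.list(f$beta), se = as.list(f$se), dispersion = f$dispersion,
    n_strata = f$n_strata, n_obs = f$n_obs, df = f$df,
    converged = f$converged, iterations = f$iterations)
  jsonlite::write_json(list(
    rirr = cmp$rirr, ci = as.list(cmp$ci),
    irr_reference = as.list(cmp$irr_ref), irr_insured = as.list(cmp$irr_ins),
    dispersion = as.list(cmp$dispersion),
    naive = list(z = cmp$naive$z, p = cmp$naive$p, rirr = cmp$naive$rirr,
                 ci = as.list(cmp$naive$ci)),
    ci_overlap_significant = cmp$ci_overlap_significant,
    fit_combined = fit_json(cmp$fit_combined),
    fit_reference = fit_json(cmp$fit_ref),
    fit_insured = fit_json(cmp$fit_ins)),
    file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
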