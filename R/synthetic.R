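## Synthetic data: climate, populations, enrollment, encounter counts with
## known ground-truth parameters. Every downstream stage is testable against
## these without restricted data.

#' Climate generator parameters
#'
#' @param mean_tmax statewide mean daily maximum temperature, degrees C.
#' @param seasonal_amplitude half peak-to-trough seasonal swing, degrees C.
#' @param ar1_rho lag-1 autocorrelation of the deseasonalized residual, in
#'   `[0, 1)`.
#' @param noise_sd innovation standard deviation of the AR(1) residual,
#'   degrees C (> 0 unless the degenerate constant-series case is wanted).
#' @param rh_mean,rh_sd mean and SD of daily relative humidity, percent;
#'   values are clipped to `[0, 100]`.
#' @param rh_temp_corr correlation between RH and the deseasonalized
#'   temperature residual, in `(-1, 1)`; hot anomalies are typically dry,
#'   hence the negative default.
#' @param county_offset_sd SD of the per-county shift in mean tmax, degrees
#'   C, giving counties distinct climates and hence distinct thresholds.
#' @return a list of class `climate_params`.
#' @export
climate_params <- function(mean_tmax = 26, seasonal_amplitude = 9,
                           ar1_rho = 0.7, noise_sd = 2.5,
                           rh_mean = 55, rh_sd = 12, rh_temp_corr = -0.4,
                           county_offset_sd = 2) {
  stopifnot(ar1_rho >= 0, ar1_rho < 1, noise_sd >= 0,
            rh_temp_corr > -1, rh_temp_corr < 1, rh_sd >= 0)
  structure(list(mean_tmax = mean_tmax, seasonal_amplitude = seasonal_amplitude,
                 ar1_rho = ar1_rho, noise_sd = noise_sd, rh_mean = rh_mean,
                 rh_sd = rh_sd, rh_temp_corr = rh_temp_corr,
                 county_offset_sd = county_offset_sd),
            class = "climate_params")
}

#' Ground-truth effect parameters for the encounter generator
#'
#' The daily count model is log-linear: the expected count in a stratum-day
#' is `person_days * baseline_rate * rate_multiplier *
#' exp(b_hw * hw + b_rh * RH + b_holiday * h)`, with dataset-specific
#' heatwave effects.
#'
#' @param log_irr_hw named numeric, log incidence-rate ratio of a heatwave
#'   day per dataset (names `reference`, `insured`).
#' @param log_rr_rh log rate ratio per 1 percentage point of relative
#'   humidity (RH enters the linear predictor untransformed, on the 0-100
#'   scale).
#' @param log_rr_holiday log rate ratio of a holiday.
#' @param baseline_rate named numeric, encounters per person-day per cause
#'   in the reference population.
#' @param overdispersion variance/mean ratio of counts at fixed covariates;
#'   1 = pure Poisson, > 1 = gamma-mixed Poisson with variance
#'   `overdispersion * mean` at every mean (the quasi-Poisson variance
#'   function).
#' @return a list of class `effect_params`.
#' @export
effect_params <- function(log_irr_hw = c(reference = log(1.1), insured = log(1.2)),
                          log_rr_rh = 0.002, log_rr_holiday = 0.05,
                          baseline_rate = c(all = 8e-4),
                          overdispersion = 1.3) {
  stopifnot(all(baseline_rate >= 0), overdispersion >= 1)
  structure(list(log_irr_hw = log_irr_hw, log_rr_rh = log_rr_rh,
                 log_rr_holiday = log_rr_holiday,
                 baseline_rate = baseline_rate,
                 overdispersion = overdispersion),
            class = "effect_params")
}

#' Coverage parameters linking the insured sub-population to the reference
#'
#' @param coverage_fraction either a single value in `(0, 1]` applied to all
#'   strata, or a function `(age_group, sex, county) -> fraction` for skewed
#'   coverage.
#' @param rate_multiplier named numeric, multiplicative shift of the
#'   baseline encounter rate per dataset (the insured population may use
#'   care at a different rate than the state-wide one).
#' @param enrollment_jitter_sd relative SD of month-to-month enrollment
#'   noise (0 = enrollment exactly `coverage_fraction * reference`).
#' @return a list of class `coverage_params`.
#' @export
coverage_params <- function(coverage_fraction = 0.034,
                            rate_multiplier = c(reference = 1, insured = 0.4),
                            enrollment_jitter_sd = 0.02) {
  if (is.numeric(coverage_fraction)) {
    stopifnot(all(coverage_fraction > 0), all(coverage_fraction <= 1))
  } else if (!is.function(coverage_fraction)) {
    stop("coverage_fraction must be numeric in (0,1] or a function")
  }
  structure(list(coverage_fraction = coverage_fraction,
                 rate_multiplier = rate_multiplier,
                 enrollment_jitter_sd = enrollment_jitter_sd),
            class = "coverage_params")
}

#' Generate daily county climate series
#'
#' Daily maximum temperature is a seasonal sinusoid (peak in mid-July) plus
#' a stationary AR(1) residual; relative humidity is correlated with the
#' same-day residual via `rh_temp_corr` and clipped to `[0, 100]`.
#' Deterministic given `seed`.
#'
#' @param counties character vector of county codes.
#' @param date_range length-2 vector (start, end), coercible to `Date`; must
#'   cover the baseline years plus the study years.
#' @param params a [climate_params()] object.
#' @param seed integer seed.
#' @return data.frame with columns `county`, `date`, `tmax_c`, `rh_pct`.
#' @export
generate_climate <- function(counties, date_range, params = climate_params(),
                             seed = 1L) {
  if (length(counties) == 0L) stop("empty county list")
  dates <- date_seq(date_range[1], date_range[2])
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- params$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  rho <- params$ar1_rho
  marg_sd <- if (params$noise_sd > 0) params$noise_sd / sqrt(1 - rho^2) else 0

  with_seed(derive_seed(seed, "climate"), {
    offs <- rnorm(length(counties), 0, params$county_offset_sd)
    out <- vector("list", length(counties))
    for (i in seq_along(counties)) {
      eps <- rnorm(nd, 0, params$noise_sd)
      ## stationary start, then the AR(1) recursion vectorized
      eps[1] <- if (marg_sd > 0) rnorm(1, 0, marg_sd) else 0
      resid <- as.numeric(stats::filter(eps, rho, method = "recursive"))
      z <- if (marg_sd > 0) resid / marg_sd else numeric(nd)
      r <- params$rh_temp_corr
      rh <- params$rh_mean + params$rh_sd *
        (r * z + sqrt(1 - r^2) * rnorm(nd))
      out[[i]] <- data.frame(
        county = counties[i], date = dates,
        tmax_c = params$mean_tmax + offs[i] + season + resid,
        rh_pct = pmin(100, pmax(0, rh)),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

## realistic-ish stratum shares: age pyramid and county size distribution
.age_shares <- c("18-24" = 0.17, "25-34" = 0.19, "35-44" = 0.16,
                 "45-54" = 0.16, "55-64" = 0.15, "65-74" = 0.10, "75+" = 0.07)

#' Generate a reference population table and a monthly enrollment table
#'
#' The reference population has log-normal county sizes, a fixed adult age
#' pyramid, and a near 50/50 sex split, constant within year with mild
#' year-on-year growth. Monthly insured enrollment is
#' `coverage_fraction * reference` per stratum with optional multiplicative
#' month-to-month jitter; all counts are non-negative integers.
#'
#' @param counties character vector of county codes.
#' @param years integer vector of study years.
#' @param coverage a [coverage_params()] object.
#' @param seed integer seed.
#' @param mean_county_pop mean county adult population.
#' @return list with `population` (county, age_group, sex, year, count) and
#'   `enrollment` (county, age_group, sex, year, month, count).
#' @export
generate_population <- function(counties, years,
                                coverage = coverage_params(), seed = 1L,
                                mean_county_pop = 2e5) {
  if (length(counties) == 0L) stop("empty county list")
  sexes <- c("F", "M")
  ages <- age_bands()
  cf <- coverage$coverage_fraction
  with_seed(derive_seed(seed, "population"), {
    csize <- exp(rnorm(length(counties), log(mean_county_pop), 0.6))
    grid <- expand.grid(county = counties, age_group = ages, sex = sexes,
                        year = years, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    growth <- 1 + 0.004 * (grid$year - min(years))
    sexshare <- ifelse(grid$sex == "F", 0.506, 0.494)
    base <- csize[match(grid$county, counties)] *
      .age_shares[grid$age_group] * sexshare * growth
    grid$count <- as.integer(round(base))
    frac <- if (is.function(cf)) {
      mapply(cf, grid$age_group, grid$sex, grid$county)
    } else rep(cf, nrow(grid))
    if (any(frac <= 0 | frac > 1)) stop("coverage_fraction outside (0, 1]")

    enr <- grid[rep(seq_len(nrow(grid)), each = 12L), ]
    enr$month <- rep(1:12, times = nrow(grid))
    fr <- rep(frac, each = 12L)
    jit <- if (coverage$enrollment_jitter_sd > 0) {
      exp(rnorm(nrow(enr), 0, coverage$enrollment_jitter_sd))
    } else 1
    enr$count <- as.integer(round(enr$count * fr * jit))
    enr <- enr[, c("county", "age_group", "sex", "year", "month", "count")]
    rownames(enr) <- NULL
    list(population = grid, enrollment = enr)
  })
}

#' Generate daily encounter counts per dataset
#'
#' Counts are drawn stratum-day by stratum-day with mean
#' `person_days * baseline_rate * rate_multiplier *
#' exp(b_hw * hw + b_rh * RH + b_holiday * h)`. Overdispersion > 1 is a
#' gamma-mixed Poisson (the Poisson rate is gamma-distributed with shape
#' `mu / (overdispersion - 1)`), giving variance `overdispersion * mean` at
#' every mean — the quasi-Poisson variance function. Deterministic given
#' `seed`.
#'
#' @param calendar heatwave calendar from [detect_heatwaves()].
#' @param climate climate table (for RH).
#' @param person_time data.frame (county, age_group, sex, date, person_days)
#'   for this dataset, e.g. from [person_time_from_population()].
#' @param effects an [effect_params()] object.
#' @param dataset `"reference"` or `"insured"`; selects the heatwave effect
#'   and rate multiplier.
#' @param holidays `Date` vector.
#' @param rate_multiplier multiplicative baseline-rate shift for this
#'   dataset (see [coverage_params()]).
#' @param encounter_type_shares named shares summing to 1 used to thin
#'   counts into encounter types.
#' @param seed integer seed.
#' @return EncounterCounts data.frame: `dataset`, `date`, `county`,
#'   `age_group`, `sex`, `cause`, `encounter_type`, `count`.
#' @export
generate_encounters <- function(calendar, climate, person_time,
                                effects = effect_params(),
                                dataset = "reference",
                                holidays = NULL,
                                rate_multiplier = 1,
                                encounter_type_shares = c(ED = 0.7, inpatient = 0.3),
                                seed = 1L) {
  assert_cols(person_time, c("county", "age_group", "sex", "date", "person_days"),
              "person_time")
  if (any(person_time$person_days < 0)) stop("negative person_time")
  if (!dataset %in% names(effects$log_irr_hw))
    stop(sprintf("no log_irr_hw entry for dataset '%s'", dataset))
  pt <- person_time
  pt$date <- as.Date(pt$date)
  calendar$date <- as.Date(calendar$date)
  climate$date <- as.Date(climate$date)
  if (is.null(holidays)) {
    holidays <- default_holidays(unique(as.integer(format(pt$date, "%Y"))))
  }

  key <- paste(pt$county, pt$date)
  calkey <- paste(calendar$county, calendar$date)
  clikey <- paste(climate$county, climate$date)
  i_cal <- match(key, calkey)
  i_cli <- match(key, clikey)
  if (anyNA(i_cal) || anyNA(i_cli))
    stop("calendar/climate do not cover all person_time county-dates")
  hw <- calendar$hw_any[i_cal]
  rh <- climate$rh_pct[i_cli]
  h <- as.integer(pt$date %in% holidays)

  lin <- effects$log_irr_hw[[dataset]] * hw + effects$log_rr_rh * rh +
    effects$log_rr_holiday * h
  od <- effects$overdispersion
  shares <- encounter_type_shares / sum(encounter_type_shares)
  if (length(shares) != 2L || !"ED" %in% names(shares))
    stop("encounter_type_shares must name exactly two types including 'ED'")

  with_seed(derive_seed(seed, paste0("counts-", dataset)), {
    out <- list()
    for (j in seq_along(effects$baseline_rate)) {
      cause <- names(effects$baseline_rate)[j]
      mu <- pt$person_days * effects$baseline_rate[[j]] * rate_multiplier *
        exp(lin)
      lam <- if (od > 1) {
        pos <- mu > 0
        l <- numeric(length(mu))
        l[pos] <- rgamma(sum(pos), shape = mu[pos] / (od - 1),
                         scale = od - 1)
        l
      } else mu
      total <- rpois(length(lam), lam)
      ## thin into encounter types
      ed <- rbinom(length(total), total, shares[["ED"]])
      for (ty in names(shares)) {
        cnt <- if (ty == "ED") ed else total - ed
        out[[length(out) + 1L]] <- data.frame(
          dataset = dataset, date = pt$date, county = pt$county,
          age_group = pt$age_group, sex = pt$sex, cause = cause,
          encounter_type = ty, count = cnt, stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)  # zero-count rows kept: referent days matter
    rownames(res) <- NULL
    res
  })
}
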