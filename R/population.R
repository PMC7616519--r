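## Person-time, standardization weights, incidence rates, demographic ratios.

#' Split a 15-19 census band into the adult age groups
#'
#' Census counts in 5-year bands have no split at age 18; 2 of the 5 single
#' years in 15-19 are 18 and 19, so a `fraction` (default 0.4) of that band
#' is moved into the 18-24 band. Deterministic mode multiplies by the
#' fraction; sampled mode draws Binomial(n, fraction) per row.
#'
#' @param raw data.frame (county, age_group, sex, year, count) containing a
#'   `"15-19"` band and a `"20-24"` band (merged into `"18-24"`).
#' @param fraction share of the 15-19 band that is 18-19 years old.
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed seed for sampled mode.
#' @return PopulationTable with the seven adult bands.
#' @export
split_age_15_19 <- function(raw, fraction = 0.4,
                            mode = c("deterministic", "sampled"), seed = 1L) {
  mode <- match.arg(mode)
  assert_cols(raw, c("county", "age_group", "sex", "year", "count"), "raw")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  teen <- raw$age_group == "15-19"
  moved <- numeric(nrow(raw))
  if (mode == "deterministic") {
    moved[teen] <- raw$count[teen] * fraction
  } else {
    moved[teen] <- with_seed(derive_seed(seed, "agesplit"),
                             rbinom(sum(teen), raw$count[teen], fraction))
  }
  out <- raw
  out$count <- ifelse(teen, moved, out$count)
  out$age_group[teen] <- "18-24"
  out$age_group[out$age_group == "20-24"] <- "18-24"
  out <- out[out$age_group %in% age_bands(), , drop = FALSE]
  agg <- group_sum(out, c("county", "age_group", "sex", "year"), "count")
  agg$year <- as.integer(agg$year)
  agg$count <- as.numeric(agg$count)
  agg
}

#' Person-time at risk from monthly enrollment
#'
#' Each calendar date in month m of year y contributes
#' `enrollment(stratum, y, m)` person-days for that stratum (the monthly
#' average enrollee count stands in for the daily population at risk).
#'
#' @param enrollment data.frame (county, age_group, sex, year, month, count).
#' @param dates `Date` vector of study dates.
#' @param strict error on dates whose month has no enrollment row (default);
#'   otherwise zero person-days with a warning.
#' @return PersonTimeTable (county, age_group, sex, date, person_days).
#' @export
person_time_from_enrollment <- function(enrollment, dates, strict = TRUE) {
  assert_cols(enrollment, c("county", "age_group", "sex", "year", "month",
                            "count"), "enrollment")
  dates <- sort(unique(as.Date(dates)))
  dm <- data.frame(date = dates,
                   year = as.integer(format(dates, "%Y")),
                   month = as.integer(format(dates, "%m")))
  strata <- unique(enrollment[c("county", "age_group", "sex")])
  out <- merge(strata, dm)
  ek <- paste(enrollment$county, enrollment$age_group, enrollment$sex,
              enrollment$year, enrollment$month)
  ok <- paste(out$county, out$age_group, out$sex, out$year, out$month)
  i <- match(ok, ek)
  if (anyNA(i)) {
    if (strict) stop("enrollment missing for some stratum-months in dates")
    warning("enrollment missing for some stratum-months; using zero")
  }
  out$person_days <- ifelse(is.na(i), 0, enrollment$count[i])
  out[, c("county", "age_group", "sex", "date", "person_days")]
}

#' Person-time at risk from annual population counts
#'
#' As [person_time_from_enrollment()] but with annual constancy: every date
#' in year y contributes `population(stratum, y)` person-days.
#'
#' @param population PopulationTable (county, age_group, sex, year, count).
#' @param dates `Date` vector of study dates.
#' @param strict error on dates in years without population rows.
#' @return PersonTimeTable.
#' @export
person_time_from_population <- function(population, dates, strict = TRUE) {
  assert_cols(population, c("county", "age_group", "sex", "year", "count"),
              "population")
  dates <- sort(unique(as.Date(dates)))
  dm <- data.frame(date = dates, year = as.integer(format(dates, "%Y")))
  strata <- unique(population[c("county", "age_group", "sex")])
  out <- merge(strata, dm)
  pk <- paste(population$county, population$age_group, population$sex,
              population$year)
  ok <- paste(out$county, out$age_group, out$sex, out$year)
  i <- match(ok, pk)
  if (anyNA(i)) {
    if (strict) stop("population missing for some stratum-years in dates")
    warning("population missing for some stratum-years; using zero")
  }
  out$person_days <- ifelse(is.na(i), 0, population$count[i])
  out[, c("county", "age_group", "sex", "date", "person_days")]
}

#' Direct-standardization weights
#'
#' Year-specific weights that re-weight insured stratum counts to the
#' reference population's stratum composition:
#' `w(s, y) = [P_ref(s, y) / sum_s P_ref] / [P_ins(s, y) / sum_s P_ins]`.
#' After re-weighting, insured stratum shares equal reference shares in
#' every year. Strata with zero insured population get weight 0 with a
#' warning (their counts cannot be re-weighted).
#'
#' @param insured,reference PopulationTables on the same (county, age_group,
#'   sex, year) strata.
#' @return data.frame (county, age_group, sex, year, weight).
#' @export
standardization_weights <- function(insured, reference) {
  for (nm in c("insured", "reference"))
    assert_cols(get(nm), c("county", "age_group", "sex", "year", "count"), nm)
  ins_tot <- tapply(insured$count, insured$year, sum)
  ref_tot <- tapply(reference$count, reference$year, sum)
  if (any(ins_tot == 0)) stop("zero insured total in at least one year")
  ik <- paste(insured$county, insured$age_group, insured$sex, insured$year)
  rk <- paste(reference$county, reference$age_group, reference$sex,
              reference$year)
  i <- match(ik, rk)
  if (anyNA(i)) stop("reference table does not cover all insured strata")
  y <- as.character(insured$year)
  ins_share <- insured$count / as.numeric(ins_tot[y])
  ref_share <- reference$count[i] / as.numeric(ref_tot[y])
  w <- ifelse(ins_share > 0, ref_share / ins_share, 0)
  if (any(ins_share == 0 & ref_share > 0))
    warning("strata with zero insured population get weight 0")
  out <- insured[c("county", "age_group", "sex", "year")]
  out$weight <- w
  attr(out, "method") <- "ratio-of-within-year-shares"
  out
}

#' Apply standardization weights to encounter counts
#'
#' Standardized count = crude count times the weight of the count's
#' (county, age_group, sex, year) stratum; outputs may be non-integer.
#'
#' @param counts EncounterCounts.
#' @param weights output of [standardization_weights()].
#' @return EncounterCounts with real-valued `count`.
#' @export
standardize_counts <- function(counts, weights) {
  assert_cols(counts, c("date", "county", "age_group", "sex", "count"),
              "counts")
  yr <- as.integer(format(as.Date(counts$date), "%Y"))
  wk <- paste(weights$county, weights$age_group, weights$sex, weights$year)
  ck <- paste(counts$county, counts$age_group, counts$sex, yr)
  i <- match(ck, wk)
  if (anyNA(i)) stop("missing standardization weight for some count strata")
  out <- counts
  out$count <- counts$count * weights$weight[i]
  out
}

#' Incidence rate per million person-days
#'
#' `IR = scale * sum(counts) / sum(person_days)` over the requested margin
#' (e.g. by cause and encounter type, or overall).
#'
#' @param counts EncounterCounts.
#' @param person_time PersonTimeTable covering the same dates.
#' @param by character vector of count columns defining the margin (default
#'   `c("cause", "encounter_type")`); `character(0)` gives the overall rate.
#' @param scale rate denominator scale, default 1e6.
#' @return data.frame with the margin columns and `rate`.
#' @export
incidence_rate <- function(counts, person_time,
                           by = c("cause", "encounter_type"), scale = 1e6) {
  pt_total <- sum(person_time$person_days)
  if (pt_total <= 0) {
    if (sum(counts$count) > 0) stop("zero person-time with nonzero counts")
    pt_total <- NA_real_
  }
  if (length(by) == 0L) {
    return(data.frame(rate = scale * sum(counts$count) / pt_total))
  }
  agg <- group_sum(counts, by, "count")
  agg$rate <- scale * as.numeric(agg$count) / pt_total
  agg$count <- NULL
  agg
}

#' Demographic comparison table between two populations
#'
#' For each category of sex, age band, and county: the percentage share of
#' each dataset's total (annual shares averaged across years) and the
#' insured/reference ratio of shares, rounded to 2 decimals at presentation.
#' Also reports the total-population ratio. Zero reference shares yield a
#' missing ratio.
#'
#' @param insured,reference PopulationTables.
#' @param digits rounding for the ratio column (default 2).
#' @return data.frame (dimension, category, insured_pct, reference_pct,
#'   ratio); the first row is the total-population ratio with counts in the
#'   share columns.
#' @export
demographic_ratio_table <- function(insured, reference, digits = 2) {
  if (nrow(insured) == 0L || nrow(reference) == 0L) stop("empty input table")
  shares <- function(pop, dim) {
    tot <- tapply(pop$count, pop$year, sum)
    sh <- group_sum(pop, c(dim, "year"), "count")
    sh$share <- 100 * as.numeric(sh$count) / as.numeric(tot[as.character(sh$year)])
    out <- tapply(sh$share, sh[[dim]], mean)  # average annual shares over years
    out
  }
  rows <- list(data.frame(
    dimension = "total", category = "total",
    insured_pct = mean(tapply(insured$count, insured$year, sum)),
    reference_pct = mean(tapply(reference$count, reference$year, sum)),
    stringsAsFactors = FALSE))
  for (dim in c("sex", "age_group", "county")) {
    si <- shares(insured, dim)
    sr <- shares(reference, dim)
    cats <- sort(union(names(si), names(sr)))
    rows[[length(rows) + 1L]] <- data.frame(
      dimension = dim, category = cats,
      insured_pct = as.numeric(si[cats]),
      reference_pct = as.numeric(sr[cats]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$ratio <- ratio_from_shares(out$insured_pct, out$reference_pct, digits)
  rownames(out) <- NULL
  out
}

#' Ratio of two percentage shares, rounded at presentation
#'
#' @param insured_share,reference_share numeric shares (or totals).
#' @param digits decimals, default 2.
#' @return rounded insured/reference ratio; `NA` where the reference share
#'   is zero or missing.
#' @export
ratio_from_shares <- function(insured_share, reference_share, digits = 2) {
  r <- ifelse(!is.na(reference_share) & reference_share > 0,
              insured_share / reference_share, NA_real_)
  round(r, digits)
}
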