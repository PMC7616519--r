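## Heatwave exposure: baseline percentile thresholds and spell detection.

#' County baseline temperature thresholds
#'
#' Computes, for each county, the year-round `q`th percentile of daily
#' maximum temperature over a baseline period. "Year-round" means all
#' calendar days contribute, not only summer days. The quantile uses the
#' linear-interpolation convention (type 7: index `1 + (n - 1) * q / 100` on
#' the sorted sample), recorded in the output attributes because thresholds
#' are sensitive to the convention.
#'
#' @param climate data.frame with columns `county`, `date`, `tmax_c`.
#' @param baseline_years integer vector of years defining the baseline period.
#' @param q percentile in (0, 100); default 97.5.
#' @return data.frame with columns `county`, `threshold_c`, plus attributes
#'   `quantile`, `baseline_years`, `method`.
#' @export
baseline_percentile <- function(climate, baseline_years, q = 97.5) {
  assert_cols(climate, c("county", "date", "tmax_c"), "climate")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100)
    stop("q must be a single percentile in (0, 100)")
  climate$date <- as.Date(climate$date)
  base <- climate[as.integer(format(climate$date, "%Y")) %in% baseline_years, ]
  if (nrow(base) == 0L) stop("no climate rows fall in the baseline years")
  counties <- sort(unique(climate$county))
  thr <- vapply(counties, function(cty) {
    x <- base$tmax_c[base$county == cty]
    if (length(x) == 0L) return(NA_real_)
    unname(quantile(x, probs = q / 100, type = 7, names = FALSE))
  }, numeric(1))
  drop <- is.na(thr)
  if (any(drop))
    warning(sprintf("excluding %d county(ies) with no baseline data: %s",
                    sum(drop), paste(counties[drop], collapse = ", ")))
  out <- data.frame(county = counties[!drop], threshold_c = unname(thr[!drop]),
                    stringsAsFactors = FALSE)
  attr(out, "quantile") <- q
  attr(out, "baseline_years") <- range(baseline_years)
  attr(out, "method") <- "type7-linear-interpolation"
  out
}

#' Detect heatwave spells
#'
#' Flags each county-day. `exceed_simple` is 1 when tmax strictly exceeds
#' the county threshold (ties do not count as exceedance). `hw_any` is 1
#' only on days belonging to a maximal run of at least `min_run` consecutive
#' exceedance days; every constituent day of a qualifying spell is flagged.
#' Gaps in the date series break runs (no imputation). First-day/later-day
#' labels are added by [label_spell_days()], which this function calls.
#'
#' @param climate data.frame with columns `county`, `date`, `tmax_c`.
#' @param thresholds output of [baseline_percentile()] (columns `county`,
#'   `threshold_c`).
#' @param min_run minimum spell length in days (default 2).
#' @return a heatwave calendar: data.frame with `county`, `date`, `hw_any`,
#'   `hw_first`, `hw_later`, `exceed_simple`.
#' @export
detect_heatwaves <- function(climate, thresholds, min_run = 2L) {
  assert_cols(climate, c("county", "date", "tmax_c"), "climate")
  assert_cols(thresholds, c("county", "threshold_c"), "thresholds")
  if (min_run < 1L) stop("min_run must be >= 1")
  climate$date <- as.Date(climate$date)
  miss <- setdiff(unique(climate$county), thresholds$county)
  if (length(miss))
    stop(sprintf("no threshold for county(ies): %s", paste(miss, collapse = ", ")))
  thr <- setNames(thresholds$threshold_c, thresholds$county)
  o <- order(climate$county, climate$date)
  cl <- climate[o, ]
  exceed <- as.integer(cl$tmax_c > thr[cl$county])

  ## run ids restart at county changes and date gaps
  n <- nrow(cl)
  newblock <- c(TRUE, cl$county[-1] != cl$county[-n] |
                  as.integer(cl$date[-1] - cl$date[-n]) != 1L)
  ## within a block, runs of consecutive exceedance
  runstart <- exceed == 1L & (newblock | c(0L, exceed[-n]) == 0L)
  runid <- ifelse(exceed == 1L, cumsum(runstart), NA_integer_)
  runlen <- integer(n)
  if (any(exceed == 1L)) {
    tab <- table(runid)
    runlen[exceed == 1L] <- as.integer(tab[as.character(runid[exceed == 1L])])
  }
  hw_any <- as.integer(exceed == 1L & runlen >= min_run)

  cal <- data.frame(county = cl$county, date = cl$date,
                    hw_any = hw_any, hw_first = 0L, hw_later = 0L,
                    exceed_simple = exceed, stringsAsFactors = FALSE)
  label_spell_days(cal)
}

#' Label first vs later days within heatwave spells
#'
#' Within each maximal run of `hw_any == 1` days (contiguous dates, same
#' county), the earliest day gets `hw_first = 1` and all subsequent days
#' `hw_later = 1`, so that `hw_first + hw_later == hw_any` everywhere.
#'
#' @param calendar a heatwave calendar with `county`, `date`, `hw_any`.
#' @return the calendar with `hw_first` and `hw_later` (re)computed.
#' @export
label_spell_days <- function(calendar) {
  assert_cols(calendar, c("county", "date", "hw_any"), "calendar")
  calendar$date <- as.Date(calendar$date)
  o <- order(calendar$county, calendar$date)
  cal <- calendar[o, ]
  n <- nrow(cal)
  if (n == 0L) {
    cal$hw_first <- integer(0); cal$hw_later <- integer(0)
    return(cal)
  }
  newblock <- c(TRUE, cal$county[-1] != cal$county[-n] |
                  as.integer(cal$date[-1] - cal$date[-n]) != 1L)
  prev_hw <- c(0L, cal$hw_any[-n])
  first <- cal$hw_any == 1L & (newblock | prev_hw == 0L)
  cal$hw_first <- as.integer(first)
  cal$hw_later <- as.integer(cal$hw_any == 1L & !first)
  rownames(cal) <- NULL
  cal
}
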