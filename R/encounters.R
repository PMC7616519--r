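## Claims -> encounters -> daily stratum counts.

#' Group claims into encounters
#'
#' Within each person, claims are chained: a claim joins the open encounter
#' when its date is at most one calendar day after the previous claim in
#' that encounter, so a run of claims on consecutive days collapses to one
#' encounter dated at the first claim. An encounter containing any
#' inpatient claim is classified inpatient; only all-ED encounters are ED.
#' When constituent claims disagree on cause, the earliest claim's cause
#' wins, ties broken alphabetically.
#'
#' @param claims data.frame with columns `person_id`, `claim_date`,
#'   `setting` (`"ED"` or `"INPATIENT"`), `county`, `age_group`, `sex`,
#'   `cause`.
#' @param gap_days maximum day gap joining two claims (default 1).
#' @return data.frame of encounters: `person_id`, `start_date`, `type`,
#'   `county`, `age_group`, `sex`, `cause`.
#' @export
group_claims_to_encounters <- function(claims, gap_days = 1L) {
  assert_cols(claims, c("person_id", "claim_date", "setting", "county",
                        "age_group", "sex", "cause"), "claims")
  if (nrow(claims) == 0L) {
    return(data.frame(person_id = character(0), start_date = as.Date(character(0)),
                      type = character(0), county = character(0),
                      age_group = character(0), sex = character(0),
                      cause = character(0), stringsAsFactors = FALSE))
  }
  d <- tryCatch(as.Date(claims$claim_date),
                error = function(e) rep(as.Date(NA), nrow(claims)))
  if (anyNA(d)) stop("malformed claim_date values")
  bad <- !claims$setting %in% c("ED", "INPATIENT")
  if (any(bad)) stop("setting must be 'ED' or 'INPATIENT'")
  cl <- claims
  cl$claim_date <- d
  o <- order(cl$person_id, cl$claim_date, cl$cause)
  cl <- cl[o, ]
  n <- nrow(cl)
  gap <- c(TRUE, cl$person_id[-1] != cl$person_id[-n] |
             as.integer(cl$claim_date[-1] - cl$claim_date[-n]) > gap_days)
  eid <- cumsum(gap)
  first <- !duplicated(eid)
  enc <- data.frame(
    person_id = cl$person_id[first],
    start_date = cl$claim_date[first],
    type = ifelse(tapply(cl$setting == "INPATIENT", eid, any)[
      as.character(unique(eid))], "inpatient", "ED"),
    county = cl$county[first],
    age_group = cl$age_group[first],
    sex = cl$sex[first],
    cause = cl$cause[first],
    stringsAsFactors = FALSE)
  rownames(enc) <- NULL
  enc
}

#' Classify an encounter's type from its constituent claim settings
#'
#' ED only when every claim is an ED claim; any inpatient claim makes the
#' whole encounter inpatient (matching how hospital discharge datasets
#' record mixed ED-to-admission episodes).
#'
#' @param settings character vector of claim settings for one encounter.
#' @return `"ED"` or `"inpatient"`.
#' @export
classify_encounter <- function(settings) {
  if (length(settings) == 0L) stop("encounter with no claims")
  if (!all(settings %in% c("ED", "INPATIENT")))
    stop("setting must be 'ED' or 'INPATIENT'")
  if (any(settings == "INPATIENT")) "inpatient" else "ED"
}

#' Aggregate encounters to daily stratum counts
#'
#' Counts encounters per (dataset, date, county, age_group, sex, cause,
#' encounter_type); the sum of counts equals the number of complete
#' encounters. Records with missing stratum fields are dropped with a
#' warning (their number is reported), or abort in strict mode.
#'
#' @param encounters output of [group_claims_to_encounters()].
#' @param dataset_label dataset name stamped on every row.
#' @param strict abort on incomplete records instead of dropping them.
#' @return EncounterCounts data.frame.
#' @export
aggregate_daily_counts <- function(encounters, dataset_label, strict = FALSE) {
  need <- c("start_date", "type", "county", "age_group", "sex", "cause")
  assert_cols(encounters, need, "encounters")
  if (nrow(encounters) == 0L) {
    return(data.frame(dataset = character(0), date = as.Date(character(0)),
                      county = character(0), age_group = character(0),
                      sex = character(0), cause = character(0),
                      encounter_type = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  inc <- rowSums(is.na(encounters[need]) |
                   (sapply(encounters[need], as.character) == "")) > 0
  if (any(inc)) {
    msg <- sprintf("%d encounter(s) with missing stratum fields", sum(inc))
    if (strict) stop(msg)
    warning(paste(msg, "dropped", sep = " - "))
    encounters <- encounters[!inc, , drop = FALSE]
  }
  e <- encounters
  e$date <- as.character(as.Date(e$start_date))
  e$one <- 1L
  agg <- group_sum(e, c("date", "county", "age_group", "sex", "cause", "type"),
                   "one")
  out <- data.frame(dataset = dataset_label, date = as.Date(agg$date),
                    county = agg$county, age_group = agg$age_group,
                    sex = agg$sex, cause = agg$cause,
                    encounter_type = agg$type, count = as.integer(agg$one),
                    stringsAsFactors = FALSE)
  out <- out[order(out$date, out$county, out$age_group, out$sex,
                   out$encounter_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
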