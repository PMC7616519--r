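## Internal helpers: seeds, dates, holidays, validation.

#' Derive an independent sub-seed from a root seed
#'
#' One root seed drives the whole pipeline; each stochastic component
#' (climate, population, counts, replicate k of an experiment) gets its own
#' stream so components can be regenerated independently. Kept strictly
#' below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @param k optional integer replicate index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9973 + as.numeric(k) * 7919) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default synthetic holiday calendar
#'
#' Fixed month-day holidays (8 per year), standing in for a jurisdiction's
#' federal-holiday list. Users analysing real data should supply their own
#' date vector.
#'
#' @param years integer vector of calendar years.
#' @return a `Date` vector.
#' @export
default_holidays <- function(years) {
  md <- c("01-01", "05-25", "07-04", "09-07", "10-12", "11-11", "11-26", "12-25")
  as.Date(unlist(lapply(years, function(y) paste(y, md, sep = "-"))))
}

## ISO weekday, Monday = 1
iso_weekday <- function(dates) {
  w <- as.POSIXlt(dates)$wday  # 0 = Sunday
  ifelse(w == 0L, 7L, w)
}

date_seq <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("inverted date range: end precedes start")
  seq(start, end, by = "day")
}

#' Warm-season mask
#'
#' TRUE for dates inside the warm-season window (inclusive), default
#' May 1 - Sep 30.
#'
#' @param dates vector coercible to `Date`.
#' @param start_md,end_md window bounds as `"MM-DD"` strings.
#' @return logical vector.
#' @export
in_warm_season <- function(dates, start_md = "05-01", end_md = "09-30") {
  md <- format(as.Date(dates), "%m-%d")
  md >= start_md & md <= end_md
}

#' Age bands used throughout
#' @return character vector of the seven adult age bands.
#' @export
age_bands <- function() {
  c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  invisible(df)
}

## grouped sum returning a data.frame; stable and dependency-free
group_sum <- function(df, by, value) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  s <- rowsum(df[[value]], key)
  keys <- do.call(rbind, strsplit(rownames(s), "\r", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out[[value]] <- as.vector(s)
  rownames(out) <- NULL
  out
}
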