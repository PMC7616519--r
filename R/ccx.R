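## Space-time-stratified case-crossover estimation: stratum construction and
## conditional quasi-Poisson fitting with the stratum intercepts eliminated
## analytically.

#' Build case-crossover strata from daily counts
#'
#' Counts are filtered to the requested cause / encounter type / dataset /
#' age groups, summed over age-sex within county-day (the main analysis;
#' set `by_age_sex = TRUE` to keep age-sex in the stratum key), restricted
#' to the warm-season window, and assigned to strata keyed by county, year,
#' month, and ISO day-of-week (Monday = 1). Every county-day in the window
#' contributes a row — days with zero encounters are the referent days —
#' and strata whose total count is zero are dropped (they carry no
#' information in the conditional likelihood); the dropped tally is
#' recorded in the `dropped_strata` attribute.
#'
#' @param counts EncounterCounts.
#' @param calendar heatwave calendar (provides the exposure columns).
#' @param climate climate table (provides RH).
#' @param holidays `Date` vector of holidays.
#' @param cause,encounter_type,dataset optional filters; `NULL` keeps all.
#' @param age_groups optional subset of age bands.
#' @param exposure exposure variant: `"hw_any"` (default), `"exceed_simple"`,
#'   or `"hw_split"` (two columns, first vs later spell days).
#' @param warm_season restrict to May 1 - Sep 30 (default TRUE).
#' @param by_age_sex keep age-sex in the stratum key instead of aggregating.
#' @param strict error when a count day lacks climate/calendar coverage.
#' @return list of strata; each element has `key`, `dates`, `N` (counts per
#'   day) and `X` (covariate matrix: exposure column(s), `rh`, `holiday`).
#'   Attribute `dropped_strata` counts all-zero strata removed.
#' @export
build_strata <- function(counts, calendar, climate, holidays = NULL,
                         cause = NULL, encounter_type = NULL, dataset = NULL,
                         age_groups = NULL, exposure = "hw_any",
                         warm_season = TRUE, by_age_sex = FALSE,
                         strict = TRUE) {
  assert_cols(counts, c("date", "county", "count"), "counts")
  cc <- counts
  cc$date <- as.Date(cc$date)
  if (!is.null(cause) && "cause" %in% names(cc))
    cc <- cc[cc$cause %in% cause, , drop = FALSE]
  if (!is.null(encounter_type) && "encounter_type" %in% names(cc))
    cc <- cc[cc$encounter_type %in% encounter_type, , drop = FALSE]
  if (!is.null(dataset) && "dataset" %in% names(cc))
    cc <- cc[cc$dataset %in% dataset, , drop = FALSE]
  if (!is.null(age_groups) && "age_group" %in% names(cc))
    cc <- cc[cc$age_group %in% age_groups, , drop = FALSE]

  calendar$date <- as.Date(calendar$date)
  climate$date <- as.Date(climate$date)
  ## day grid: all county-days with exposure data (zero-count days included)
  grid <- calendar[c("county", "date")]
  if (warm_season) grid <- grid[in_warm_season(grid$date), , drop = FALSE]
  if (is.null(holidays))
    holidays <- default_holidays(unique(as.integer(format(grid$date, "%Y"))))

  groupcols <- c("county", if (by_age_sex) c("age_group", "sex"), "date")
  cc$date <- as.character(cc$date)
  daily <- group_sum(cc, groupcols, "count")
  daily$date <- as.Date(daily$date)

  if (strict) {
    chk <- if (warm_season) daily[in_warm_season(daily$date), , drop = FALSE]
           else daily
    if (!all(paste(chk$county, chk$date) %in%
               paste(calendar$county, calendar$date)))
      stop("counts contain county-days missing from the exposure calendar")
  }

  if (by_age_sex) {
    ag <- unique(daily[c("age_group", "sex")])
    grid <- merge(grid, ag)
  }
  key_grid <- if (by_age_sex)
    paste(grid$county, grid$age_group, grid$sex, grid$date) else
      paste(grid$county, grid$date)
  key_daily <- if (by_age_sex)
    paste(daily$county, daily$age_group, daily$sex, daily$date) else
      paste(daily$county, daily$date)
  N <- as.numeric(daily$count)[match(key_grid, key_daily)]
  N[is.na(N)] <- 0

  calkey <- paste(calendar$county, calendar$date)
  clikey <- paste(climate$county, climate$date)
  gk <- paste(grid$county, grid$date)
  ical <- match(gk, calkey)
  icli <- match(gk, clikey)
  if (anyNA(icli)) {
    if (strict) stop("climate does not cover all calendar county-days")
    grid <- grid[!is.na(icli), ]; N <- N[!is.na(icli)]
    ical <- ical[!is.na(icli)]; icli <- icli[!is.na(icli)]
  }

  Xexp <- switch(exposure,
    hw_any = cbind(hw = calendar$hw_any[ical]),
    exceed_simple = cbind(hw = calendar$exceed_simple[ical]),
    hw_split = cbind(hw_first = calendar$hw_first[ical],
                     hw_later = calendar$hw_later[ical]),
    stop(sprintf("unknown exposure variant '%s'", exposure)))
  X <- cbind(Xexp, rh = climate$rh_pct[icli],
             holiday = as.integer(grid$date %in% holidays))

  skey <- paste(grid$county,
                if (by_age_sex) paste(grid$age_group, grid$sex) else "",
                format(grid$date, "%Y"), format(grid$date, "%m"),
                iso_weekday(grid$date))
  o <- order(skey, grid$date)
  skey <- skey[o]; N <- N[o]; X <- X[o, , drop = FALSE]
  dt <- grid$date[o]
  idx <- split(seq_along(skey), skey)
  strata <- lapply(names(idx), function(k) {
    ii <- idx[[k]]
    list(key = k, dates = dt[ii], N = N[ii], X = X[ii, , drop = FALSE])
  })
  tot <- vapply(strata, function(s) sum(s$N), numeric(1))
  out <- strata[tot > 0]
  attr(out, "dropped_strata") <- sum(tot == 0)
  attr(out, "exposure") <- exposure
  attr(out, "weekday_convention") <- "ISO (Monday = 1)"
  out
}

## stack a strata list into (N, X, g) with g the stratum index
stack_strata <- function(strata) {
  N <- unlist(lapply(strata, `[[`, "N"), use.names = FALSE)
  X <- do.call(rbind, lapply(strata, `[[`, "X"))
  g <- rep(seq_along(strata),
           vapply(strata, function(s) length(s$N), integer(1)))
  list(N = N, X = X, g = factor(g))
}

#' Conditional quasi-Poisson regression with eliminated stratum intercepts
#'
#' Maximizes the stratum-conditioned Poisson log-likelihood
#' \deqn{\ell(\beta) = \sum_s [ \sum_t N_{ts} x_{ts}'\beta
#'   - (\sum_t N_{ts}) \log \sum_t \exp(x_{ts}'\beta) ],}
#' the profile likelihood of a Poisson model with one free intercept per
#' stratum (so the point estimates coincide with a stratum-dummy Poisson
#' fit, at a fraction of the cost). Fitting is Newton-Raphson with
#' step-halving from \eqn{\beta = 0}. Quasi-likelihood dispersion is the
#' Pearson statistic over residual degrees of freedom
#' `df = n_obs - n_strata - n_params` (the eliminated intercepts count as
#' estimated parameters), with fitted means
#' \eqn{\hat\mu_{ts} = n_s \, \mathrm{softmax}_s(X\hat\beta)}; the
#' covariance is `dispersion * inverse observed information`. Non-integer
#' outcomes (standardized counts) are accepted: the quasi-score equations
#' are unchanged.
#'
#' @param strata list from [build_strata()] (or any list of `list(N, X)`
#'   elements). Strata with zero total count are ignored.
#' @param exposure_columns columns of `X` treated as exposures (defaults to
#'   all). An exposure column constant within every stratum raises a
#'   non-identifiability error; a non-exposure column constant within every
#'   stratum is dropped with a warning (it is absorbed by the stratum
#'   intercepts), leaving the remaining estimates unchanged.
#' @param max_iter,score_tol,ll_tol Newton controls; convergence when the
#'   maximum absolute score drops below `score_tol` or the relative
#'   log-likelihood change below `ll_tol`.
#' @return object of class `ccx_fit`: `beta`, `se`, `cov`, `dispersion`,
#'   `loglik`, `n_strata`, `n_obs`, `df`, `converged`, `iterations`.
#' @export
fit_conditional_poisson <- function(strata, exposure_columns = NULL,
                                    max_iter = 50L, score_tol = 1e-10,
                                    ll_tol = 1e-10) {
  keep <- vapply(strata, function(s) sum(s$N) > 0, logical(1))
  strata <- strata[keep]
  if (length(strata) == 0L) stop("no informative strata (all totals zero)")
  st <- stack_strata(strata)
  N <- st$N; X <- st$X; g <- st$g
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  ## identifiability: a column constant within every stratum is absorbed by
  ## the eliminated intercepts. Exposure columns must vary (error); other
  ## controls are dropped with a warning, leaving the rest unchanged.
  varies <- vapply(seq_len(p), function(j) {
    v <- tapply(X[, j], g, function(x) max(x) - min(x))
    any(v > 0)
  }, logical(1))
  expo <- exposure_columns %||% colnames(X)
  bad_expo <- intersect(colnames(X)[!varies], expo)
  if (length(bad_expo))
    stop(sprintf("exposure column(s) constant within every stratum (not identifiable under conditioning): %s",
                 paste(bad_expo, collapse = ", ")))
  if (any(!varies)) {
    warning(sprintf("dropping stratum-constant covariate(s): %s",
                    paste(colnames(X)[!varies], collapse = ", ")))
    X <- X[, varies, drop = FALSE]
    p <- ncol(X)
  }

  gi <- as.integer(g)                      # 1..K, strata in level order
  n_s <- as.numeric(rowsum(N, gi))         # stratum totals
  sumNx <- colSums(N * X)                  # sufficient statistics

  ## per-stratum softmax quantities at a given beta (max-shifted for
  ## numerical stability)
  state <- function(beta) {
    eta <- drop(X %*% beta)
    mg <- as.numeric(tapply(eta, gi, max))
    w <- exp(eta - mg[gi])
    S <- as.numeric(rowsum(w, gi))
    mu <- n_s[gi] * w / S[gi]
    ll <- sum(N * eta) - sum(n_s * (log(S) + mg))
    list(mu = mu, ll = ll)
  }
  loglik <- function(beta) state(beta)$ll

  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  small_prev <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- state(beta)$mu
    score <- sumNx - colSums(mu * X)
    sums <- rowsum(mu * X, gi)             # n_s * xbar_s
    info <- crossprod(X, mu * X) - crossprod(sums / sqrt(n_s))
    if (max(abs(score)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, score), error = function(e) {
      warning("ill-conditioned information; adding ridge jitter 1e-10")
      solve(info + diag(1e-10, p), score)
    })
    ## step-halving on the conditional log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { llc <- ll; cand <- beta; break }
    }
    ## quadratic convergence: demand two consecutive negligible changes so
    ## the final iterate gets one full extra Newton refinement
    small <- abs(llc - ll) < ll_tol * (abs(ll) + 1)
    beta <- cand; ll <- llc
    if (small && small_prev) { converged <- TRUE; break }
    small_prev <- small
  }
  ## final quantities at beta-hat
  mu <- state(beta)$mu
  score <- sumNx - colSums(mu * X)
  sums <- rowsum(mu * X, gi)
  info <- crossprod(X, mu * X) - crossprod(sums / sqrt(n_s))
  if (max(abs(score)) < score_tol) converged <- TRUE
  if (!converged) warning("Newton iterations did not converge")

  n_obs <- length(N)
  n_strata <- nlevels(g)
  df <- n_obs - n_strata - p
  pearson <- sum((N - mu)^2 / mu)
  dispersion <- if (df > 0) pearson / df else NA_real_
  covb <- tryCatch(solve(info), error = function(e)
    solve(info + diag(1e-10, p)))
  covu <- (covb + t(covb)) / 2                   # unscaled (phi = 1)
  covd <- if (is.finite(dispersion)) dispersion * covu else covu
  structure(list(
    beta = setNames(beta, colnames(X)),
    se = setNames(sqrt(diag(covd)), colnames(X)),
    cov = covd, cov_unscaled = covu,
    dispersion = dispersion, pearson = pearson, loglik = ll,
    n_strata = n_strata, n_obs = n_obs, df = df,
    converged = converged, iterations = iter,
    exposure_columns = exposure_columns %||% colnames(X)),
    class = "ccx_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ccx_fit <- function(x, ...) {
  cat("Conditional quasi-Poisson case-crossover fit\n")
  cat(sprintf("  strata: %d   observations: %d   dispersion: %.3f\n",
              x$n_strata, x$n_obs, x$dispersion))
  z <- x$beta / x$se
  tab <- data.frame(estimate = x$beta, se = x$se, z = z,
                    p = 2 * pnorm(-abs(z)))
  print(round(tab, 4))
  invisible(x)
}

#' Incidence rate ratio with Wald 95% CI
#'
#' `IRR = exp(beta)` with `CI = exp(beta +/- z * SE)`; the SE comes from the
#' dispersion-scaled covariance.
#'
#' @param fit a `ccx_fit`.
#' @param column coefficient name (e.g. `"hw"`).
#' @param level confidence level, default 0.95.
#' @return data.frame with `term`, `irr`, `lo`, `hi`, `beta`, `se`.
#' @export
irr <- function(fit, column = "hw", level = 0.95) {
  if (!column %in% names(fit$beta))
    stop(sprintf("no coefficient '%s' in fit", column))
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$beta[[column]]; s <- fit$se[[column]]
  data.frame(term = column, irr = exp(b), lo = exp(b - z * s),
             hi = exp(b + z * s), beta = b, se = s,
             stringsAsFactors = FALSE)
}
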