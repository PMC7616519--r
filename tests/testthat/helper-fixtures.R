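# Shared fixture builders and independent oracles. Oracles here are
# deliberately brute-force and share no code with the implementation paths
# they check.

## random case-crossover strata (small, always informative)
rand_strata <- function(n_strata, seed, p_hw = 0.3, base_log_rate = 1,
                        b = c(hw = 0.2, rh = 0.005, holiday = -0.1)) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_strata), function(k) {
      n <- sample(3:8, 1)
      X <- cbind(hw = rbinom(n, 1, p_hw), rh = rnorm(n, 50, 10),
                 holiday = rbinom(n, 1, 0.1))
      N <- rpois(n, exp(base_log_rate + drop(X %*% b)))
      list(key = paste0("s", k), dates = as.Date("2018-06-01") + seq_len(n),
           N = N, X = X)
    })
    out[vapply(out, function(s) sum(s$N) > 0, logical(1))]
  })
}

## stratum-dummy unconditional Poisson ML: the independent route to the same
## estimates (profile-likelihood equivalence)
glm_oracle <- function(strata) {
  N <- unlist(lapply(strata, `[[`, "N"))
  X <- do.call(rbind, lapply(strata, `[[`, "X"))
  g <- factor(rep(seq_along(strata),
                  vapply(strata, function(s) length(s$N), integer(1))))
  df <- data.frame(N = N, X, g = g)
  fm <- stats::as.formula(paste("N ~", paste(colnames(X), collapse = " + "), "+ g"))
  fit <- stats::glm(fm, data = df, family = stats::quasipoisson(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  p <- ncol(X)
  list(beta = stats::coef(fit)[2:(p + 1)],
       se = sqrt(diag(stats::vcov(fit)))[2:(p + 1)],
       dispersion = summary(fit)$dispersion)
}

## brute-force run-length heatwave oracle for one county's contiguous series
rle_oracle <- function(tmax, threshold, min_run = 2) {
  exceed <- as.integer(tmax > threshold)
  r <- rle(exceed)
  hw <- rep(as.integer(r$values == 1 & r$lengths >= min_run), r$lengths)
  list(exceed = exceed, hw_any = hw)
}

## sort-and-interpolate percentile oracle (type-7 convention, by hand)
quantile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + (n - 1) * q / 100
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

## union-find oracle for the claims "within 1 day" chaining relation
unionfind_oracle <- function(person_id, claim_date) {
  n <- length(person_id)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && person_id[i] == person_id[j] &&
        abs(as.integer(claim_date[i] - claim_date[j])) <= 1) {
      parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## tiny claims table generator
rand_claims <- function(n_people, seed, max_claims = 5) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_people), function(p) {
      k <- sample(seq_len(max_claims), 1)
      data.frame(person_id = sprintf("p%03d", p),
                 claim_date = as.Date("2018-07-01") + sort(sample(0:12, k)),
                 setting = sample(c("ED", "INPATIENT"), k, replace = TRUE),
                 county = "C001", age_group = "35-44", sex = "F",
                 cause = sample(c("all", "heat"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

## small two-dataset study shared by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(n_counties = 6, years = 2018:2019, seed = 2024)
    cache
  }
})
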