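# Synthetic climate, population, and encounter-count generators.

test_that("degenerate climate parameters give a constant series", {
  p <- climate_params(mean_tmax = 25, seasonal_amplitude = 0, noise_sd = 0,
                      county_offset_sd = 0)
  clim <- generate_climate("C1", c("2018-01-01", "2018-03-01"), p, seed = 1)
  expect_true(all(clim$tmax_c == 25))
})

test_that("climate generation is deterministic given the seed", {
  a <- generate_climate(c("A", "B"), c("2018-01-01", "2018-06-30"), seed = 42)
  b <- generate_climate(c("A", "B"), c("2018-01-01", "2018-06-30"), seed = 42)
  expect_identical(a, b)
  c2 <- generate_climate(c("A", "B"), c("2018-01-01", "2018-06-30"), seed = 43)
  expect_false(identical(a$tmax_c, c2$tmax_c))
})

test_that("deseasonalized tmax has the requested lag-1 autocorrelation", {
  p <- climate_params(seasonal_amplitude = 0, ar1_rho = 0.7,
                      county_offset_sd = 0)
  clim <- generate_climate("C1", c("1990-01-01", "2017-05-18"), p, seed = 3)
  expect_gte(nrow(clim), 10000)
  x <- clim$tmax_c - mean(clim$tmax_c)
  r1 <- sum(x[-1] * x[-length(x)]) / sum(x^2)
  expect_lt(abs(r1 - 0.7), 0.05)
})

test_that("climate errors on empty counties or inverted ranges", {
  expect_error(generate_climate(character(0), c("2018-01-01", "2018-02-01")),
               "empty county")
  expect_error(generate_climate("A", c("2018-02-01", "2018-01-01")),
               "inverted date range")
})

test_that("RH stays within [0, 100] and tracks the temperature residual", {
  p <- climate_params(seasonal_amplitude = 0, rh_temp_corr = -0.6,
                      county_offset_sd = 0)
  clim <- generate_climate("C1", c("2000-01-01", "2009-12-31"), p, seed = 9)
  expect_true(all(clim$rh_pct >= 0 & clim$rh_pct <= 100))
  r <- cor(clim$tmax_c, clim$rh_pct)
  expect_lt(abs(r - (-0.6)), 0.1)
})

test_that("identity coverage makes enrollment equal the reference", {
  cov1 <- coverage_params(coverage_fraction = 1, enrollment_jitter_sd = 0)
  pop <- generate_population(c("A", "B"), 2018, coverage = cov1, seed = 4)
  key_p <- paste(pop$population$county, pop$population$age_group,
                 pop$population$sex, pop$population$year)
  key_e <- paste(pop$enrollment$county, pop$enrollment$age_group,
                 pop$enrollment$sex, pop$enrollment$year)
  expect_equal(pop$enrollment$count,
               pop$population$count[match(key_e, key_p)])
})

test_that("constant coverage fraction is recovered from totals", {
  cov <- coverage_params(coverage_fraction = 0.05, enrollment_jitter_sd = 0)
  pop <- generate_population(c("A", "B", "C"), 2018:2019, coverage = cov,
                             seed = 4)
  ratio <- sum(pop$enrollment$count) / (12 * sum(pop$population$count))
  expect_equal(ratio, 0.05, tolerance = 1e-3)  # integer rounding only
})

test_that("skewed coverage shifts enrollment age shares as specified", {
  young <- c("18-24", "25-34", "35-44")
  cf <- function(age_group, sex, county) if (age_group %in% young) 0.10 else 0.05
  pop <- generate_population(c("A", "B"), 2018,
                             coverage = coverage_params(coverage_fraction = cf,
                                                        enrollment_jitter_sd = 0),
                             seed = 8)
  ref_young <- sum(pop$population$count[pop$population$age_group %in% young]) /
    sum(pop$population$count)
  enr_young <- sum(pop$enrollment$count[pop$enrollment$age_group %in% young]) /
    sum(pop$enrollment$count)
  ## expected enrolled young share under 2x coverage of young strata
  expected <- 2 * ref_young / (2 * ref_young + (1 - ref_young))
  expect_gt(enr_young, ref_young)
  expect_equal(enr_young, expected, tolerance = 0.01)
})

test_that("coverage outside (0, 1] is rejected", {
  expect_error(coverage_params(coverage_fraction = 0))
  expect_error(coverage_params(coverage_fraction = 1.2))
  cf <- function(age_group, sex, county) 1.5
  expect_error(generate_population("A", 2018,
                                   coverage = coverage_params(coverage_fraction = cf)),
               "outside")
})

test_that("zero baseline rate gives all-zero counts; totals conserved", {
  sim <- small_sim()
  eff0 <- effect_params(baseline_rate = c(all = 0))
  enc <- generate_encounters(sim$calendar, sim$climate, sim$person_time_ref,
                             eff0, dataset = "reference", seed = 1)
  expect_true(all(enc$count == 0))

  enc1 <- sim$counts_ref
  expect_true(all(enc1$count >= 0))
  by_cty <- tapply(enc1$count, enc1$county, sum)
  expect_equal(sum(by_cty), sum(enc1$count))  # stratum counts sum to total
})

test_that("null effects recover the baseline rate within Monte-Carlo error", {
  sim <- small_sim()
  eff <- effect_params(log_irr_hw = c(reference = 0, insured = 0),
                       log_rr_rh = 0, log_rr_holiday = 0,
                       baseline_rate = c(all = 8e-4), overdispersion = 1)
  enc <- generate_encounters(sim$calendar, sim$climate, sim$person_time_ref,
                             eff, dataset = "reference", seed = 21)
  expected <- sum(sim$person_time_ref$person_days) * 8e-4
  total <- sum(enc$count)
  expect_equal(total / expected, 1, tolerance = 4 / sqrt(expected))
})

test_that("the generated crude heatwave rate ratio matches the true IRR", {
  ## isolate the heatwave effect: no RH or holiday effect
  eff <- effect_params(log_irr_hw = c(reference = log(1.2), insured = log(1.2)),
                       log_rr_rh = 0, log_rr_holiday = 0,
                       baseline_rate = c(all = 8e-4))
  sim <- simulate_study(n_counties = 40, years = 2015:2018, effects = eff,
                        seed = 31)
  enc <- sim$counts_ref
  key <- paste(enc$county, enc$date)
  calkey <- paste(sim$calendar$county, sim$calendar$date)
  hw <- sim$calendar$hw_any[match(key, calkey)]
  pt <- sim$person_time_ref
  ptk <- paste(pt$county, pt$age_group, pt$sex, pt$date)
  ek <- paste(enc$county, enc$age_group, enc$sex, enc$date)
  pd <- pt$person_days[match(ek, ptk)]
  rate_hw <- sum(enc$count[hw == 1]) / sum(pd[hw == 1]) * 2  # 2 type rows/stratum
  rate_no <- sum(enc$count[hw == 0]) / sum(pd[hw == 0]) * 2
  expect_gt(rate_hw / rate_no, 1.15)
  expect_lt(rate_hw / rate_no, 1.25)
})

test_that("pure-Poisson counts have unit index of dispersion", {
  ## identical covariates across replicates: fixed climate, no effects
  p <- climate_params(seasonal_amplitude = 0, noise_sd = 0,
                      county_offset_sd = 0, rh_sd = 0)
  clim <- generate_climate("C1", c("2018-06-01", "2018-06-01"), p, seed = 1)
  cal <- data.frame(county = "C1", date = as.Date("2018-06-01"), hw_any = 0L,
                    hw_first = 0L, hw_later = 0L, exceed_simple = 0L)
  pt <- data.frame(county = "C1", age_group = "35-44", sex = "F",
                   date = as.Date("2018-06-01"), person_days = 5e4)
  eff <- effect_params(log_rr_rh = 0, log_rr_holiday = 0,
                       baseline_rate = c(all = 4e-4), overdispersion = 1)
  counts <- vapply(1:60, function(r) {
    enc <- generate_encounters(cal, clim, pt, eff, dataset = "reference",
                               seed = 1000 + r)
    sum(enc$count)
  }, numeric(1))
  n <- length(counts)
  stat <- (n - 1) * var(counts) / mean(counts)  # ~ chi-square(n-1) under Poisson
  expect_gt(stat, qchisq(0.005, n - 1))
  expect_lt(stat, qchisq(0.995, n - 1))
})

test_that("overdispersed counts have variance near overdispersion x mean", {
  p <- climate_params(seasonal_amplitude = 0, noise_sd = 0,
                      county_offset_sd = 0, rh_sd = 0)
  clim <- generate_climate("C1", c("2018-06-01", "2018-06-01"), p, seed = 1)
  cal <- data.frame(county = "C1", date = as.Date("2018-06-01"), hw_any = 0L,
                    hw_first = 0L, hw_later = 0L, exceed_simple = 0L)
  pt <- data.frame(county = "C1", age_group = "35-44", sex = "F",
                   date = as.Date("2018-06-01"), person_days = 5e4)
  eff <- effect_params(log_rr_rh = 0, log_rr_holiday = 0,
                       baseline_rate = c(all = 4e-4), overdispersion = 2)
  counts <- vapply(1:400, function(r) {
    enc <- generate_encounters(cal, clim, pt, eff, dataset = "reference",
                               seed = 5000 + r)
    sum(enc$count)
  }, numeric(1))
  expect_equal(var(counts) / mean(counts), 2, tolerance = 0.35)
})

test_that("encounter generation rejects negative person-time", {
  sim <- small_sim()
  pt <- sim$person_time_ref
  pt$person_days[1] <- -1
  expect_error(generate_encounters(sim$calendar, sim$climate, pt,
                                   effect_params(), dataset = "reference"),
               "negative")
})
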