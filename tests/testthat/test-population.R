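# Person-time, standardization, incidence rates, demographic ratios.

pop_tab <- function(counts, ages = names(counts), county = "C1", sex = "F",
                    year = 2018) {
  data.frame(county = county, age_group = ages, sex = sex, year = year,
             count = as.numeric(counts), stringsAsFactors = FALSE)
}

test_that("the 15-19 band split moves the stated fraction into 18-24", {
  raw <- data.frame(county = "C1", age_group = c("15-19", "20-24", "25-34"),
                    sex = "F", year = 2018, count = c(1000, 500, 800),
                    stringsAsFactors = FALSE)
  out <- split_age_15_19(raw)
  expect_equal(out$count[out$age_group == "18-24"], 400 + 500)
  out0 <- split_age_15_19(raw, fraction = 0)
  expect_equal(out0$count[out0$age_group == "18-24"], 500)
  expect_error(split_age_15_19(raw, fraction = 1.5), "fraction")
  ## total conserved over the adult bands plus what stays behind
  expect_equal(sum(out$count), 400 + 500 + 800)
})

test_that("sampled split has binomial moments", {
  raw <- data.frame(county = "C1", age_group = "15-19", sex = "F",
                    year = 2018, count = 1000, stringsAsFactors = FALSE)
  moved <- vapply(1:2000, function(r) {
    out <- split_age_15_19(raw, mode = "sampled", seed = r)
    out$count[out$age_group == "18-24"]
  }, numeric(1))
  expect_equal(mean(moved), 400, tolerance = 4 * sqrt(240 / 2000) / 400)
  expect_equal(var(moved), 240, tolerance = 0.25)
})

test_that("person-time from enrollment multiplies out over calendar days", {
  enr <- data.frame(county = "C1", age_group = "35-44", sex = "F",
                    year = 2018, month = 6, count = 100,
                    stringsAsFactors = FALSE)
  dates <- seq(as.Date("2018-06-01"), as.Date("2018-06-30"), by = "day")
  pt <- person_time_from_enrollment(enr, dates)
  expect_equal(sum(pt$person_days), 3000)
  enr0 <- transform(enr, count = 0)
  expect_equal(sum(person_time_from_enrollment(enr0, dates)$person_days), 0)
  expect_error(person_time_from_enrollment(enr, as.Date("2018-07-04")),
               "missing")
})

test_that("annual person-time sums to 365 (or 366) times the count", {
  pop <- pop_tab(c("35-44" = 50), year = 2018)
  d18 <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  expect_equal(sum(person_time_from_population(pop, d18)$person_days), 365 * 50)
  pop20 <- transform(pop, year = 2020)
  d20 <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  expect_equal(sum(person_time_from_population(pop20, d20)$person_days), 366 * 50)
})

test_that("identical distributions give unit weights; shares as hand-computed", {
  ins <- pop_tab(c("18-24" = 100, "25-34" = 300))
  ref <- pop_tab(c("18-24" = 1000, "25-34" = 3000))
  w <- standardization_weights(ins, ref)
  expect_equal(w$weight, c(1, 1))

  ins2 <- pop_tab(c("18-24" = 80, "25-34" = 20))
  ref2 <- pop_tab(c("18-24" = 50, "25-34" = 50))
  w2 <- standardization_weights(ins2, ref2)
  expect_equal(w2$weight, c(0.625, 2.5))
  ## normalization forced by the formula
  expect_equal(sum(w2$weight * c(0.8, 0.2)), 1)
})

test_that("re-weighted insured shares equal reference shares to 1e-9", {
  withr::with_seed(17, {
    grid <- expand.grid(county = c("A", "B", "C"), age_group = age_bands(),
                        sex = c("F", "M"), year = 2018:2019,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ref <- grid; ref$count <- rpois(nrow(grid), 5000) + 1
    ins <- grid; ins$count <- rpois(nrow(grid), 200) + 1
  })
  w <- standardization_weights(ins, ref)
  std <- ins$count * w$weight
  for (y in 2018:2019) {
    iy <- ins$year == y
    expect_equal(std[iy] / sum(std[iy]),
                 ref$count[iy] / sum(ref$count[iy]), tolerance = 1e-9)
  }
})

test_that("standardizing counts multiplies by the stratum-year weight", {
  counts <- data.frame(dataset = "ins", date = as.Date("2018-07-04"),
                       county = "C1", age_group = "18-24", sex = "F",
                       cause = "all", encounter_type = "ED", count = 10,
                       stringsAsFactors = FALSE)
  w <- data.frame(county = "C1", age_group = "18-24", sex = "F", year = 2018,
                  weight = 2.5, stringsAsFactors = FALSE)
  expect_equal(standardize_counts(counts, w)$count, 25)
  w1 <- transform(w, weight = 1)
  expect_equal(standardize_counts(counts, w1), counts)
  expect_error(standardize_counts(transform(counts, age_group = "75+"), w),
               "missing standardization weight")
})

test_that("incidence rates follow the definition and a groupby oracle", {
  counts <- data.frame(cause = "all", encounter_type = "ED", count = 1)
  pt <- data.frame(person_days = 1e6)
  expect_equal(incidence_rate(counts, pt)$rate, 1)
  expect_equal(incidence_rate(transform(counts, count = 0), pt)$rate, 0)
  expect_error(incidence_rate(counts, transform(pt, person_days = 0)),
               "zero person-time")

  withr::with_seed(23, {
    rc <- data.frame(cause = sample(c("all", "heat"), 200, TRUE),
                     encounter_type = sample(c("ED", "inpatient"), 200, TRUE),
                     count = rpois(200, 3))
    rpt <- data.frame(person_days = runif(50, 100, 1000))
  })
  got <- incidence_rate(rc, rpt)
  for (i in seq_len(nrow(got))) {
    sel <- rc$cause == got$cause[i] & rc$encounter_type == got$encounter_type[i]
    expect_equal(got$rate[i], 1e6 * sum(rc$count[sel]) / sum(rpt$person_days))
  }
  ## scale equivariance
  rc2 <- transform(rc, count = 2 * count)
  expect_equal(incidence_rate(rc2, rpt)$rate, 2 * got$rate)
  rpt2 <- transform(rpt, person_days = 2 * person_days)
  expect_equal(incidence_rate(rc, rpt2)$rate, got$rate / 2)
})

test_that("identical populations give all demographic ratios 1", {
  withr::with_seed(31, {
    grid <- expand.grid(county = c("A", "B"), age_group = age_bands(),
                        sex = c("F", "M"), year = 2018:2019,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$count <- rpois(nrow(grid), 1000) + 1
  })
  tab <- demographic_ratio_table(grid, grid)
  expect_true(all(tab$ratio == 1))
})

test_that("ratio of shares reproduces published-style comparison cells", {
  expect_equal(ratio_from_shares(20.5, 18.6), 1.10)
  expect_equal(ratio_from_shares(10.7, 4.9), 2.18)
  expect_true(is.na(ratio_from_shares(5, 0)))
})

test_that("demographic table shares average annual shares across years", {
  ins <- rbind(pop_tab(c("18-24" = 100, "25-34" = 100), year = 2018),
               pop_tab(c("18-24" = 300, "25-34" = 100), year = 2019))
  ref <- rbind(pop_tab(c("18-24" = 100, "25-34" = 300), year = 2018),
               pop_tab(c("18-24" = 100, "25-34" = 300), year = 2019))
  tab <- demographic_ratio_table(ins, ref)
  ## insured 18-24 shares: 50% and 75% -> 62.5%; reference constant 25%
  r <- tab[tab$dimension == "age_group" & tab$category == "18-24", ]
  expect_equal(r$insured_pct, 62.5)
  expect_equal(r$reference_pct, 25)
  expect_equal(r$ratio, 2.5)
})
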