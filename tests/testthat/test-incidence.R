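## hand-built panel + status for subcohort event resolution
mini_cohort <- function() {
  ## 9 biennial waves; person 1: dementia-free at wave 5 (2010.5), first
  ## dementia at wave 6 (2012.5); person 2: dies 3 years after wave 5;
  ## person 3: dementia-free throughout
  dates <- seq(2002.5, 2018.5, by = 2)
  panel <- do.call(rbind, lapply(1:9, function(w) {
    data.frame(id = 1:3, wave = w, date = dates[w], age = 60 + dates[w] - 2002.5,
               female = c(0, 1, 1), education = "middle")
  }))
  panel <- panel[!(panel$id == 2 & panel$date > 2013.5), ]
  st_state <- with(panel, id == 1 & wave >= 6)
  status <- list(status = data.frame(id = panel$id, wave = panel$wave,
                                     dementia = st_state, dementia_abs = st_state),
                 first_wave = data.frame(id = 1:3,
                                         first_wave = c(6L, NA, NA)))
  class(status) <- "dementia_status"
  deaths <- data.frame(id = 2L, death_date = 2013.5)
  list(panel = panel, status = status, deaths = deaths)
}

test_that("events resolve with midpoint onset imputation, death dates, and 4-year censoring", {
  mc <- mini_cohort()
  rec <- build_subcohorts(mc$panel, mc$status, deaths = mc$deaths)
  r5 <- rec[rec$subcohort == 5, ]
  ## person 1: onset midpoint of 2010.5 and 2012.5 = 2011.5, 1 person-year
  expect_equal(r5$event[r5$id == 1], "dementia")
  expect_equal(r5$onset_date[r5$id == 1], 2011.5)
  expect_equal(r5$time[r5$id == 1], 1.0)
  ## person 2: death 3 years after baseline, no dementia
  expect_equal(r5$event[r5$id == 2], "death")
  expect_equal(r5$time[r5$id == 2], 3.0)
  ## person 3: administratively censored at 4 years
  expect_equal(r5$event[r5$id == 3], "censored")
  expect_equal(r5$time[r5$id == 3], 4.0)
  ## person 1 is excluded from subcohorts at and after their dementia wave
  expect_false(1 %in% rec$id[rec$subcohort == 6])
})

test_that("the nine-wave biennial design yields exactly seven subcohorts", {
  rec <- shared_records()
  expect_equal(sort(unique(rec$subcohort)), 1:7)
  ## everyone enters dementia-free, aged 50+, with positive person-years <= 4
  expect_true(all(rec$age >= 50))
  expect_true(all(rec$time > 0 & rec$time <= 4))
  ## a person observed dementia-free through two baselines is in both
  in12 <- intersect(rec$id[rec$subcohort == 1], rec$id[rec$subcohort == 2])
  expect_gt(length(in12), 0)
})

test_that("crude rate is cases over person-years, scaled", {
  rec <- data.frame(event = c(rep("dementia", 5), rep("censored", 120)),
                    time = c(rep(4, 5), rep(4, 120)))
  expect_equal(crude_rate(rec), 5 / 500 * 1000)
  rec0 <- data.frame(event = rep("censored", 10), time = rep(2, 10))
  expect_equal(crude_rate(rec0), 0)
  expect_error(crude_rate(data.frame(event = character(), time = numeric())),
               "person-years")
})

test_that("crude rate recovers a constant generating intensity", {
  ## constant q01 = 0.01/yr, no onset-measurement noise: crude subcohort
  ## rate approximates 10 per 1000 py (midpoint imputation, death competing)
  cfg <- clean_cfg(n_core = 4000, seed = 31,
                   base_intensities = list(q01 = 0.01, q02 = 0.02, q12 = NULL),
                   rel_mort_dementia = 1,
                   age_coefs = c(q01 = 0, q02 = 0, q12 = 0),
                   sex_coefs = c(q01 = 0, q02 = 0, q12 = 0),
                   trend_spec = list(ref_year = 2002, break_year = 2008,
                                     slope_pre = 0, slope_post = 0))
  pd <- simulate_panel(cfg)
  rec <- build_subcohorts(pd, ascertain_dementia(pd))
  n_cases <- sum(rec$event == "dementia")
  rate <- crude_rate(rec)
  se <- 1000 * sqrt(n_cases) / sum(rec$time)
  expect_lt(abs(rate - 10), 3 * se)
})

test_that("direct standardisation is a weighted mean of stratum rates", {
  ## two strata (men 60s, women 60s), rates 10 and 20 per 1000 py
  rec <- rbind(
    data.frame(age = 62, female = 0, time = 1,
               event = c(rep("dementia", 10), rep("censored", 990))),
    data.frame(age = 62, female = 1, time = 1,
               event = c(rep("dementia", 20), rep("censored", 980))))
  std_eq <- data.frame(age_lo = 60, age_hi = 64, female = c(0, 1),
                       weight = c(1, 1))
  expect_equal(standardised_rate(rec, std_eq), 15)
  std_31 <- data.frame(age_lo = 60, age_hi = 64, female = c(0, 1),
                       weight = c(3, 1))
  expect_equal(standardised_rate(rec, std_31), 12.5)
  ## invariance: uniform rates give the common rate under any weights
  rec_u <- rec[rec$female == 0, ]
  rec_u2 <- rec_u; rec_u2$female <- 1
  std_any <- data.frame(age_lo = 60, age_hi = 64, female = c(0, 1),
                        weight = c(7, 2))
  expect_equal(standardised_rate(rbind(rec_u, rec_u2), std_any), 10)
  ## empty positively-weighted stratum drops with a warning
  std_extra <- rbind(std_eq, data.frame(age_lo = 90, age_hi = 99, female = 0,
                                        weight = 5))
  expect_warning(standardised_rate(rec, std_extra), "renormalised")
})

test_that("subgroup rates partition the totals", {
  rec <- shared_records()
  for (by in c("age", "sex", "education")) {
    t <- subgroup_rates(rec, by)
    expect_equal(sum(t$cases), sum(rec$event == "dementia"))
    expect_equal(sum(t$person_years), sum(rec$time))
  }
  expect_error(subgroup_rates(rec, "bogus"))
})

test_that("education-specific onset intensities are recovered in rank order", {
  ## q01 of 0.012 / 0.008 / 0.006 for low / middle / high education
  cfg <- cohort_config(n_core = 6000, refresh_waves = no_refresh(),
                       base_intensities = list(q01 = 0.008, q02 = 0.02, q12 = NULL),
                       edu_coefs = c(low = log(0.012 / 0.008), middle = 0,
                                     high = log(0.006 / 0.008)),
                       age_coefs = c(q01 = 0, q02 = 0.09, q12 = 0.09),
                       trend_spec = list(ref_year = 2002, break_year = 2008,
                                         slope_pre = 0, slope_post = 0),
                       measurement_spec = noiseless_measurement(), seed = 17)
  pd <- simulate_panel(cfg)
  rec <- build_subcohorts(pd, ascertain_dementia(pd))
  t <- subgroup_rates(rec, "education")
  r <- setNames(t$rate, t$group)
  expect_gt(r["low"], r["middle"])
  expect_gt(r["middle"], r["high"])
})

test_that("incidence table mirrors the subcohort-by-rate layout", {
  tab <- incidence_table(shared_records())
  expect_equal(nrow(tab), 7L)
  expect_true(all(c("crude", "standardised", "sex_women", "sex_men",
                    "education_low") %in% names(tab)))
  expect_true(all(tab$crude > 0))
})
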