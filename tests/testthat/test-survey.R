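sib_row <- function(alive, interview = 2019.0, current_age = NA,
                    age_at_death = NA, years_since_death = NA,
                    birth_date = NA, death_date = NA) {
  data.frame(respondent_id = 1L, weight = 1, sib_sex = "female",
             alive = alive, current_age = current_age,
             age_at_death = age_at_death,
             years_since_death = years_since_death,
             birth_date = as.numeric(birth_date),
             death_date = as.numeric(death_date),
             interview_date = interview)
}

test_that("sibling dates are imputed with the midpoint convention", {
  r <- impute_sibling_dates(sib_row(FALSE, 2019.0, age_at_death = 30,
                                    years_since_death = 4))
  expect_equal(r$death_date, 2014.5)
  expect_equal(r$birth_date, 1984.0)

  r2 <- impute_sibling_dates(sib_row(TRUE, 2019.0, current_age = 25))
  expect_equal(r2$birth_date, 1993.5)

  explicit <- sib_row(FALSE, 2019.0, age_at_death = 30, years_since_death = 4,
                      birth_date = 1983.2, death_date = 2013.9)
  expect_equal(impute_sibling_dates(explicit)$birth_date, 1983.2)
  expect_equal(impute_sibling_dates(explicit)$death_date, 2013.9)

  bad <- rbind(sib_row(FALSE), sib_row(TRUE, current_age = 40))
  expect_message(out <- impute_sibling_dates(bad), "1 unusable")
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "n_unusable"), 1L)
})

test_that("sibling exposure splits person-years exactly across cells", {
  alive <- sib_row(TRUE, 2019.5, current_age = 29)
  alive$birth_date <- 1990.0
  ex <- sibling_exposure(alive, period = c(2010, 2015))
  expect_equal(ex$person_years, c(0, 5, rep(0, 5)))   # all in 20-24
  expect_equal(sum(ex$deaths), 0)

  dead <- sib_row(FALSE, 2019.5, age_at_death = 22, years_since_death = 7)
  dead$birth_date <- 1990.0
  dead$death_date <- 2012.0
  ex2 <- sibling_exposure(dead, period = c(2010, 2015))
  expect_equal(ex2$person_years, c(0, 2, rep(0, 5)))
  expect_equal(ex2$deaths, c(0, 1, rep(0, 5)))

  empty <- sibling_exposure(alive[0, ], period = c(2010, 2015))
  expect_true(all(empty$person_years == 0) && all(empty$deaths == 0))

  expect_error(sibling_exposure(alive, period = c(2015, 2010)), "exceed")
})

test_that("exposure matches the segment-enumeration oracle", {
  withr::with_seed(71, {
    rec <- random_sibling_records(1000)
    period <- c(2005.3, 2017.8)
    ex <- sibling_exposure(rec, period)
    end_obs <- ifelse(rec$alive, rec$interview_date, rec$death_date)
    breaks <- c(seq(15, 45, 5), 50)
    want <- oracle_exposure(rec$birth_date, end_obs, rec$weight, period, breaks)
    expect_equal(ex$person_years, want, tolerance = 1e-6)
    expect_equal(sum(ex$person_years), sum(want), tolerance = 1e-9)
  })
})

test_that("deaths land only in the cell of their date and age", {
  withr::with_seed(72, {
    rec <- random_sibling_records(2000)
    period <- c(2008, 2016)
    ex <- sibling_exposure(rec, period)
    age_d <- rec$death_date - rec$birth_date
    in_scope <- !rec$alive & rec$death_date >= period[1] &
      rec$death_date < period[2] & age_d >= 15 & age_d < 50
    expect_equal(sum(ex$deaths), sum(rec$weight[in_scope]), tolerance = 1e-9)
  })
})

test_that("direct 35q15 is invariant to weight scale and record order", {
  withr::with_seed(73, {
    rec <- random_sibling_records(3000)
    period <- c(2004.5, 2019.5)
    e1 <- direct_35q15(sibling_exposure(rec, period), n_boot = 0)
    rec2 <- rec; rec2$weight <- rec2$weight * 3.7
    e2 <- direct_35q15(sibling_exposure(rec2, period), n_boot = 0)
    expect_equal(e2$estimate, e1$estimate, tolerance = 1e-12)
    rec3 <- rec[sample.int(nrow(rec)), ]
    e3 <- direct_35q15(sibling_exposure(rec3, period), n_boot = 0)
    expect_equal(e3$estimate, e1$estimate, tolerance = 1e-12)
  })
})

test_that("direct 35q15 handles zero deaths and reports empty cells", {
  withr::with_seed(74, {
    rec <- random_sibling_records(3000)
    rec$alive <- TRUE; rec$death_date <- NA_real_
    rec$current_age <- floor(rec$interview_date - rec$birth_date)
    ex <- sibling_exposure(rec, c(2004.5, 2019.5))
    expect_equal(direct_35q15(ex, n_boot = 0)$estimate, 0)
  })
  one <- sib_row(TRUE, 2019.5, current_age = 20)
  one$birth_date <- 1999.0
  ex1 <- sibling_exposure(one, c(2015, 2019))
  expect_error(direct_35q15(ex1), "zero exposure in age cell")
})

test_that("household rates tabulate deaths over exact person-years", {
  n <- 1000
  survivors <- data.frame(household_id = 1:(n - 10), weight = 1,
                          sex = "female", age = 25 - 1e-9, died = FALSE,
                          death_date = NA_real_, survey_date = 2018.5)
  dead <- data.frame(household_id = (n - 9):n, weight = 1, sex = "female",
                     age = 25 - 1e-6, died = TRUE,
                     death_date = 2018.5 - 1e-6, survey_date = 2018.5)
  est <- household_rates(rbind(survivors, dead), 2018.5, window_years = 5)
  M <- est$by_sex$female$rates$M
  expect_equal(M[ages(est$by_sex$female$rates$grid) == 20], 10 / 5000,
               tolerance = 1e-4)
  expect_equal(est$mid_period, 2016)

  survivors$died <- FALSE
  est0 <- household_rates(survivors, 2018.5)
  expect_true(all(est0$by_sex$female$rates$M == 0))
  expect_equal(est0$by_sex$female$q1550, 0)
  expect_null(est0$by_sex$female$life_table)   # open interval not closable

  expect_error(household_rates(survivors, 2018.5, window_years = 0), "positive")
  bad <- dead; bad$death_date <- 2010
  expect_error(household_rates(rbind(survivors, bad), 2018.5),
               "outside the lookback window")
})

test_that("household rates recover a known schedule at scale", {
  sch <- gompertz_rate_schedule(1e-4, 0.085)
  hh <- make_household_survey(100000, sch, 2018.5, seed = 77)
  est <- household_rates(hh, 2018.5)
  for (sx in c("female", "male")) {
    M_hat <- est$by_sex[[sx]]$rates$M
    old <- which(ages(sch$grid) >= 55)   # cells with hundreds of deaths
    expect_true(all(abs(M_hat[old] - sch$M[old]) / sch$M[old] <= 0.15))
    expect_false(is.na(est$by_sex[[sx]]$e15))
  }
  expect_equal(est$e15_gap, 0, tolerance = 1.5)  # same schedule both sexes
})

test_that("weight screening applies a strict-inequality threshold", {
  tab <- data.frame(weight = c(rep(NA_real_, 96), rep(1, 4)))
  expect_message(v <- screen_survey_weights(tab), "dropped")
  expect_false(v$usable)
  expect_equal(v$missing_fraction, 0.96)

  ok <- data.frame(weight = rep(1, 50))
  expect_true(screen_survey_weights(ok)$usable)

  at <- data.frame(weight = c(rep(NA_real_, 5), rep(1, 5)))
  expect_true(screen_survey_weights(at)$usable)    # exactly at threshold

  expect_error(screen_survey_weights(data.frame(x = 1)), "no column")
})
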