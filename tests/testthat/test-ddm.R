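# shared deterministic scenarios
stable_sc <- make_ddm_scenario(scenario_truth(r = 0.01, c = 1, t = 10))
stationary_sc <- make_ddm_scenario(scenario_truth(r = 0, c = 1, t = 10))

scale_deaths <- function(ds, s) {
  death_series(ds$grid, ds$sex, ds$period_start, ds$period_end, ds$deaths * s)
}

test_that("intercensal inputs recover growth rates and are scale invariant", {
  g <- age_grid(seq(0, 75, 5), 80)
  N <- seq(9e4, 1e3, length.out = 17)
  D <- N * 0.02 * 10
  cp0 <- census_pair(g, "total", 2000, 2010, N, N)
  ds0 <- death_series(g, "total", 2000, 2010, D)
  ii0 <- intercensal_inputs(cp0, ds0)
  expect_equal(ii0$r_plus, rep(0, 17), tolerance = 1e-12)

  cp1 <- census_pair(g, "total", 2000, 2010, N, N * exp(0.02 * 10))
  ii1 <- intercensal_inputs(cp1, ds0)
  expect_equal(ii1$r_plus, rep(0.02, 17), tolerance = 1e-12)

  cp2 <- census_pair(g, "total", 2000, 2010, 2 * N, 2 * N)
  ds2 <- scale_deaths(ds0, 2)
  ii2 <- intercensal_inputs(cp2, ds2)
  expect_equal(ii2$entry_rate, ii0$entry_rate, tolerance = 1e-12)
  expect_equal(ii2$death_rate, ii0$death_rate, tolerance = 1e-12)

  Nz <- N; Nz[16:17] <- 0
  expect_error(intercensal_inputs(census_pair(g, "total", 2000, 2010, Nz, Nz),
                                  ds0),
               "zero cumulated population above age 75")
})

test_that("GGB recovers completeness and relative census coverage", {
  ii <- intercensal_inputs(stable_sc$cp, stable_sc$ds)
  f <- ggb_fit(ii, c(15, 80))
  expect_false(f$degenerate)
  expect_equal(f$C, 1, tolerance = 0.02)
  expect_equal(f$intercept, 0, tolerance = 0.01)

  ds07 <- scale_deaths(stable_sc$ds, 0.7)
  f07 <- ggb_fit(intercensal_inputs(stable_sc$cp, ds07), c(15, 80))
  expect_equal(f07$C, 0.7, tolerance = 0.02)

  sc9 <- make_ddm_scenario(scenario_truth(r = 0.01, c = 1, k2 = 0.9, t = 10))
  f9 <- ggb_fit(intercensal_inputs(sc9$cp, sc9$ds), c(15, 80))
  expect_equal(f9$rel_coverage, 1 / 0.9, tolerance = 0.03 / 1.11)

  # orthogonal fit agrees closely on clean data
  fo <- ggb_fit(ii, c(15, 80), fit = "orthogonal")
  expect_equal(fo$C, f$C, tolerance = 0.01)
})

test_that("degenerate GGB fits are flagged, not clipped", {
  ii <- intercensal_inputs(stable_sc$cp, stable_sc$ds)
  few <- ggb_fit(ii, c(15, 25))   # two points only
  expect_true(few$degenerate)
  expect_true(is.na(few$C))
})

test_that("SEG reproduces the stationary identity and scales with deaths", {
  ii <- intercensal_inputs(stationary_sc$cp, stationary_sc$ds)
  s <- seg_estimate(ii, stationary_sc$cp, stationary_sc$ds, c(15, 80))
  in_win <- which(s$age >= 15 & s$age < 80)
  expect_true(all(abs(s$ratios[in_win] - 1) <= 0.02))

  ds08 <- scale_deaths(stationary_sc$ds, 0.8)
  s08 <- seg_estimate(intercensal_inputs(stationary_sc$cp, ds08),
                      stationary_sc$cp, ds08, c(15, 80))
  expect_equal(s08$C, 0.8, tolerance = 0.02)

  # exact linearity when the closure is held fixed
  sf1 <- seg_estimate(ii, stationary_sc$cp, stationary_sc$ds, c(15, 80),
                      open_closure_e = 7)
  ds06 <- scale_deaths(stationary_sc$ds, 0.6)
  sf2 <- seg_estimate(intercensal_inputs(stationary_sc$cp, ds06),
                      stationary_sc$cp, ds06, c(15, 80), open_closure_e = 7)
  expect_equal(sf2$C, 0.6 * sf1$C, tolerance = 1e-12)

  # synthetic population decreases in age when deaths are positive everywhere
  expect_true(all(diff(s$N_hat) < 0))

  ds_zero <- stationary_sc$ds
  ds_zero$deaths[17] <- 0
  expect_error(seg_estimate(intercensal_inputs(stationary_sc$cp, ds_zero),
                            stationary_sc$cp, ds_zero, c(15, 80)),
               "closure impossible")
})

test_that("GGB-SEG equals SEG after the coverage adjustment it estimates", {
  ii <- intercensal_inputs(stable_sc$cp, stable_sc$ds)
  gs <- ggbseg_estimate(ii, stable_sc$cp, stable_sc$ds, c(15, 80))
  # composition identity: manually adjusting census 2 by the fitted k1/k2
  # and running plain SEG gives the same estimate
  k1k2 <- gs$ggb$rel_coverage
  cp_adj <- census_pair(stable_sc$cp$grid, "total", 2000, 2010,
                        stable_sc$cp$N1, stable_sc$cp$N2 * k1k2)
  s_adj <- seg_estimate(intercensal_inputs(cp_adj, stable_sc$ds), cp_adj,
                        stable_sc$ds, c(15, 80))
  expect_equal(gs$C, s_adj$C, tolerance = 1e-12)
  # a coverage ratio of exactly 1 is a no-op adjustment
  cp_noop <- census_pair(stable_sc$cp$grid, "total", 2000, 2010,
                         stable_sc$cp$N1, stable_sc$cp$N2 * 1.0)
  s_noop <- seg_estimate(intercensal_inputs(cp_noop, stable_sc$ds), cp_noop,
                         stable_sc$ds, c(15, 80))
  s_plain <- seg_estimate(ii, stable_sc$cp, stable_sc$ds, c(15, 80))
  expect_identical(s_noop$C, s_plain$C)
  # with k1 = k2 both routes estimate the true completeness
  expect_equal(gs$C, 1, tolerance = 0.03)
  expect_equal(s_plain$C, 1, tolerance = 0.03)
})

test_that("GGB-SEG absorbs census undercount that biases plain SEG", {
  sc <- make_ddm_scenario(scenario_truth(r = 0.01, c = 1, k2 = 0.9, t = 10))
  ii <- intercensal_inputs(sc$cp, sc$ds)
  s_plain <- seg_estimate(ii, sc$cp, sc$ds, c(15, 80))
  expect_gt(abs(s_plain$C - 1), 0.03)   # plain SEG biased away from 1
  expect_equal(ggbseg_estimate(ii, sc$cp, sc$ds, c(15, 80))$C, 1,
               tolerance = 0.03)

  sc6 <- make_ddm_scenario(scenario_truth(r = 0.01, c = 0.6, k2 = 0.9, t = 10))
  ii6 <- intercensal_inputs(sc6$cp, sc6$ds)
  expect_equal(ggbseg_estimate(ii6, sc6$cp, sc6$ds, c(15, 80))$C, 0.6,
               tolerance = 0.03)
})

test_that("trim windows are enumerated combinatorially", {
  g13 <- age_grid(seq(0, 75, 5), 80)
  w <- enumerate_trim_windows(g13, min_groups = 8, low = 15, high_end = 80)
  expect_identical(nrow(w), 21L)     # sum over lengths 8..13 of (13 - L + 1)
  expect_true(all(w$high - w$low >= 40))
  expect_true(all(w$low >= 15 & w$high <= 80))

  g10 <- age_grid(seq(0, 60, 5), 65)
  w10 <- enumerate_trim_windows(g10, min_groups = 8, low = 15, high_end = 65)
  expect_identical(nrow(w10), 6L)    # 3 + 2 + 1

  expect_error(enumerate_trim_windows(age_grid(seq(0, 40, 5), 45),
                                      min_groups = 8),
               "no admissible window")
})

test_that("the trim sweep is consistent, nested and scale invariant", {
  sw <- trim_sweep(stable_sc$cp, stable_sc$ds, "ggbseg")
  expect_lte(sw$max - sw$min, 0.05)  # age-constant completeness
  expect_true(sw$min <= sw$mean && sw$mean <= sw$max)
  full <- ggbseg_estimate(intercensal_inputs(stable_sc$cp, stable_sc$ds),
                          stable_sc$cp, stable_sc$ds, c(15, 80))
  expect_true(full$C >= sw$min - 1e-12 && full$C <= sw$max + 1e-12)

  cp5 <- census_pair(stable_sc$cp$grid, "total", 2000, 2010,
                     stable_sc$cp$N1 * 5, stable_sc$cp$N2 * 5)
  ds5 <- scale_deaths(stable_sc$ds, 5)
  for (m in c("ggb", "seg", "ggbseg")) {
    expect_equal(trim_sweep(cp5, ds5, m)$per_window$C,
                 trim_sweep(stable_sc$cp, stable_sc$ds, m)$per_window$C,
                 tolerance = 1e-9)
  }
})

test_that("completeness-adjusted rates scale as 1/C and move 35q15 monotonically", {
  cp <- stable_sc$cp; ds <- stable_sc$ds
  r1 <- adjust_rates(ds, cp, C = 1)
  PY <- cp$t * sqrt(cp$N1 * cp$N2)
  expect_equal(r1$M, ds$deaths / PY, tolerance = 1e-12)
  r08 <- adjust_rates(ds, cp, C = 0.8)
  expect_equal(r08$M, r1$M * 1.25, tolerance = 1e-12)
  expect_error(adjust_rates(ds, cp, C = 0), "positive")

  q <- vapply(seq(0.5, 1.1, by = 0.1), function(C) {
    prob_15_50(build_life_table(adjust_rates(ds, cp, C)))
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})
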