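# independent oracles and shared fixtures, built in code

# brute-force person-time oracle: enumerate every breakpoint (period bounds,
# cell boundaries, start/stop of observation) and assign each elementary
# segment to the cell containing its midpoint -- scalar arithmetic, no shared
# code with the vectorised implementation
oracle_exposure <- function(birth, end_obs, weight, period, breaks) {
  ncell <- length(breaks) - 1L
  py <- numeric(ncell)
  for (i in seq_along(birth)) {
    lo <- max(birth[i] + breaks[1L], period[1])
    hi <- min(end_obs[i], period[2])
    if (hi <= lo) next
    cuts <- sort(unique(c(lo, hi, birth[i] + breaks)))
    cuts <- cuts[cuts >= lo & cuts <= hi]
    for (s in seq_len(length(cuts) - 1L)) {
      mid_age <- (cuts[s] + cuts[s + 1L]) / 2 - birth[i]
      j <- findInterval(mid_age, breaks)
      if (j >= 1L && j <= ncell) {
        py[j] <- py[j] + weight[i] * (cuts[s + 1L] - cuts[s])
      }
    }
  }
  py
}

# product-form oracle for the probability of dying between 15 and 50
oracle_q1550 <- function(M, a = rep(2.5, length(M))) {
  q <- 5 * M / (1 + (5 - a) * M)
  1 - prod(1 - q)
}

# random valid rate schedule on the default grid
random_schedule <- function(grid = age_grid(seq(0, 75, 5), 80)) {
  k <- length(ages(grid))
  M <- stats::runif(k, 1e-4, 0.08)
  M[k] <- stats::runif(1, 0.05, 0.3)
  rate_schedule(grid, M)
}

# random date-complete sibling record set
random_sibling_records <- function(n, interview = 2019.5) {
  birth <- interview - stats::runif(n, 1, 70)
  dead <- stats::runif(n) < 0.3
  death <- ifelse(dead, birth + stats::runif(n, 0, interview - birth), NA_real_)
  data.frame(respondent_id = sample.int(max(1, n %/% 3), n, replace = TRUE),
             weight = stats::runif(n, 0.2, 3),
             sib_sex = sample(c("female", "male"), n, replace = TRUE),
             alive = !dead,
             current_age = ifelse(dead, NA_real_, floor(interview - birth)),
             age_at_death = ifelse(dead, floor(death - birth), NA_real_),
             years_since_death = ifelse(dead, floor(interview - death), NA_real_),
             birth_date = birth, death_date = death,
             interview_date = interview)
}

# Gompertz level calibrated so the stationary life table has a given 35q15
calibrate_alpha <- function(target_q1550, beta = 0.08,
                            grid = age_grid(seq(0, 75, 5), 80)) {
  stats::uniroot(function(a) {
    prob_15_50(build_life_table(gompertz_rate_schedule(a, beta, grid))) -
      target_q1550
  }, c(1e-6, 5e-3), tol = 1e-12)$root
}
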