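# Synthetic-data generators with known ground truth.
#
# All generators are pure functions of (parameters, seed).  The DDM scenario
# is built from a stable population under a Gompertz adult hazard
# mu(x) = alpha * exp(beta * x): two parameters are enough to span realistic
# adult mortality levels, and the stable age structure n(a) = B exp(-r a) l(a)
# is exactly the premise the two-census methods assume.

# composite-Simpson quadrature of f over [lo, hi] (vectorised f)
simpson <- function(f, lo, hi, n = 2048L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(lo, hi, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (hi - lo) / (3 * n)
}

gompertz_mu <- function(x, alpha, beta) alpha * exp(beta * x)
gompertz_l <- function(x, alpha, beta) {
  if (beta == 0) exp(-alpha * x) else exp(-(alpha / beta) * (exp(beta * x) - 1))
}

#' Stationary rate schedule implied by a Gompertz hazard
#'
#' Group central rates `M(x) = integral(mu * l) / integral(l)` over each
#' interval of the grid, i.e. the rates of the stationary population exposed
#' to the hazard `mu(x) = alpha * exp(beta * x)`.
#'
#' @param alpha,beta Gompertz level (per year, > 0) and shape (per year,
#'   >= 0) parameters.
#' @param grid An [age_grid()] (default 0-4 ... 75-79 plus 80+).
#' @param sex Label carried on the schedule.
#' @param max_age Upper integration bound standing in for infinity.
#' @return A [rate_schedule()].
#' @export
gompertz_rate_schedule <- function(alpha, beta,
                                   grid = age_grid(seq(0, 75, 5), 80),
                                   sex = "total", max_age = 130) {
  stopifnot(alpha > 0, beta >= 0)
  x <- ages(grid)
  k <- n_intervals(grid)
  up <- c(x[-1L], max_age)
  M <- vapply(seq_len(k), function(i) {
    py <- simpson(function(a) gompertz_l(a, alpha, beta), x[i], up[i])
    dx <- simpson(function(a) gompertz_mu(a, alpha, beta) *
                    gompertz_l(a, alpha, beta), x[i], up[i])
    dx / py
  }, numeric(1))
  rate_schedule(grid, M, sex = sex)
}

#' Ground-truth parameters of a two-census DDM scenario
#'
#' @param r Stable population growth rate (per year).
#' @param alpha,beta Gompertz hazard parameters (see
#'   [gompertz_rate_schedule()]).  The defaults give adult mortality in the
#'   range typical of middle-income countries.
#' @param c Death-registration completeness in (0, 1].
#' @param k1,k2 Census enumeration coverages in (0, 1].
#' @param t Intercensal length in years.
#' @param grid An [age_grid()]; default 0-4 ... 75-79 plus 80+, matching the
#'   trim-sweep range.
#' @param completeness_by_age Optional per-interval completeness vector
#'   overriding the age-constant `c` (sets the age-varying flag).
#' @param migration Optional per-interval net migration rates (per year);
#'   applied as a census-2 distortion `exp(m * t)` while deaths are left at
#'   their closed-population values — a deliberate violation of the
#'   closed-to-migration assumption for negative-control testing.
#' @param pop_scale Total (true) population at census 1.
#' @return An object of class `scenario_truth`.
#' @export
scenario_truth <- function(r = 0.01, alpha = 1e-4, beta = 0.085, c = 1,
                           k1 = 1, k2 = 1, t = 10,
                           grid = age_grid(seq(0, 75, 5), 80),
                           completeness_by_age = NULL, migration = NULL,
                           pop_scale = 1e7) {
  stopifnot(inherits(grid, "age_grid"))
  if (!(c > 0 && c <= 1)) stopf("completeness c must be in (0, 1]")
  if (!(k1 > 0 && k1 <= 1) || !(k2 > 0 && k2 <= 1)) {
    stopf("census coverages k1, k2 must be in (0, 1]")
  }
  if (!(t > 1 && t < 30)) stopf("intercensal length t must be in (1, 30)")
  if (alpha <= 0 || beta < 0) stopf("hazard parameters out of range")
  k <- n_intervals(grid)
  if (!is.null(completeness_by_age) && length(completeness_by_age) != k) {
    stopf("completeness_by_age must have one value per interval")
  }
  if (!is.null(migration) && length(migration) != k) {
    stopf("migration must have one net rate per interval")
  }
  structure(list(r = r, alpha = alpha, beta = beta, c = c, k1 = k1, k2 = k2,
                 t = t, grid = grid,
                 completeness_by_age = completeness_by_age,
                 age_constant = is.null(completeness_by_age),
                 migration = migration, pop_scale = pop_scale),
            class = "scenario_truth")
}

#' Generate a deterministic two-census DDM scenario
#'
#' Builds the stable age distribution `n(a) = B exp(-r a) l(a)` implied by
#' the truth parameters, integrates it over the grid, and derives:
#' census 1 = `k1 * N`, census 2 = `k2 * N * exp(r t)`, true intercensal
#' deaths from person-years times the hazard under constant rates, and
#' registered deaths = `c *` true deaths (exactly, by construction).
#' Optional Poisson noise replaces the registered counts by Poisson draws
#' with those expectations.
#'
#' @param truth A [scenario_truth()].
#' @param seed RNG seed; only consumed when `poisson = TRUE`.
#' @param poisson Draw Poisson-distributed registered deaths instead of
#'   deterministic expected counts.
#' @return An object of class `scenario_data`: `cp` ([census_pair()]),
#'   `ds` ([death_series()]) and `truth`, where `truth` is augmented with
#'   exact boundary-age quantities (`n_exact`, `P_plus`, `D_plus_annual`),
#'   the true rate schedule, true 35q15 / e15, and the true life expectancy
#'   at the open age.
#' @export
make_ddm_scenario <- function(truth, seed = 1, poisson = FALSE) {
  stopifnot(inherits(truth, "scenario_truth"))
  grid <- truth$grid
  k <- n_intervals(grid)
  x <- ages(grid)
  max_age <- 130
  up <- c(x[-1L], max_age)
  dens <- function(a) exp(-truth$r * a) * gompertz_l(a, truth$alpha, truth$beta)
  ddens <- function(a) gompertz_mu(a, truth$alpha, truth$beta) * dens(a)

  G <- vapply(seq_len(k), function(i) simpson(dens, x[i], up[i]), numeric(1))
  DG <- vapply(seq_len(k), function(i) simpson(ddens, x[i], up[i]), numeric(1))
  B <- truth$pop_scale / sum(G)     # radix of the stable density
  G <- B * G
  DG <- B * DG

  # period scaling: integral over (0, t) of exp(r s) ds
  tau <- if (truth$r == 0) truth$t else (exp(truth$r * truth$t) - 1) / truth$r

  N1 <- truth$k1 * G
  N2 <- truth$k2 * G * exp(truth$r * truth$t)
  if (!is.null(truth$migration)) {
    N2 <- N2 * exp(truth$migration * truth$t)
  }
  true_deaths <- DG * tau
  cvec <- if (truth$age_constant) rep(truth$c, k) else truth$completeness_by_age
  reg <- cvec * true_deaths
  if (poisson) {
    reg <- with_seed(seed, stats::rpois(k, reg))
  }

  cp <- census_pair(grid, "total", date1 = 2000, date2 = 2000 + truth$t,
                    N1 = N1, N2 = N2)
  ds <- death_series(grid, "total", 2000, 2000 + truth$t, reg)

  # exact boundary-age quantities for identity checks
  n_exact <- B * dens(x)
  P_plus <- vapply(x, function(a) B * simpson(dens, a, max_age), numeric(1))
  D_plus_annual <- vapply(x, function(a) B * simpson(ddens, a, max_age), numeric(1))
  true_rates <- gompertz_rate_schedule(truth$alpha, truth$beta, grid = grid)
  # note: in the stable population group rates equal integral(mu n)/integral(n),
  # which differs slightly from the stationary schedule; store the stable ones
  true_rates$M <- DG / G
  lt <- build_life_table(true_rates)
  e_open_true <- simpson(function(a) gompertz_l(a, truth$alpha, truth$beta),
                         grid$open_age, max_age) /
    gompertz_l(grid$open_age, truth$alpha, truth$beta)

  truth_out <- truth
  truth_out$seed <- seed
  truth_out$poisson <- poisson
  truth_out$tau <- tau
  truth_out$n_exact <- n_exact
  truth_out$P_plus <- P_plus
  truth_out$D_plus_annual <- D_plus_annual
  truth_out$true_deaths <- true_deaths
  truth_out$rates <- true_rates
  truth_out$q1550 <- prob_15_50(lt)
  truth_out$e15 <- lt$e[match(15, lt$age)]
  truth_out$e_open <- e_open_true
  structure(list(cp = cp, ds = ds, truth = truth_out),
            class = "scenario_data")
}

#' Exact growth-balance plotting coordinates of a scenario
#'
#' Computes the GGB regression coordinates from the scenario's exact
#' boundary-age quantities (not from grouped census counts), on the observed
#' coverage scale.  In the deterministic, closed, age-constant case these
#' points lie exactly on a straight line whose slope and intercept are
#' analytic functions of (c, k1, k2, r, t); both are returned alongside.
#'
#' @param sc A `scenario_data` from [make_ddm_scenario()].
#' @return A list with vectors `x`, `y` (one point per interval start) and
#'   the analytic `slope` and `intercept` of the line they lie on.
#' @export
scenario_ggb_coords <- function(sc) {
  stopifnot(inherits(sc, "scenario_data"))
  tr <- sc$truth
  if (!tr$age_constant) stopf("exact coordinates require age-constant completeness")
  t <- tr$t
  grow <- exp(tr$r * t)
  # observed-scale entry and person-years share the factor sqrt(k1 k2 grow),
  # which cancels; the registered-death coordinate keeps c / sqrt(k1 k2 grow)
  y <- tr$n_exact / tr$P_plus - (tr$r + log(tr$k2 / tr$k1) / t)
  xc <- tr$c * (tr$tau / t) * tr$D_plus_annual /
    (sqrt(tr$k1 * tr$k2 * grow) * tr$P_plus)
  slope <- sqrt(tr$k1 * tr$k2 * grow) * t / (tr$c * tr$tau)
  intercept <- log(tr$k1 / tr$k2) / t
  list(x = xc, y = y, slope = slope, intercept = intercept)
}

# inverse-lifetable sampling of an exact age at death
draw_death_age <- function(lt, n) {
  k <- nrow(lt)
  radix <- lt$l[1L]
  i <- sample.int(k, n, replace = TRUE, prob = lt$d / radix)
  open <- i == k
  age <- numeric(n)
  age[!open] <- lt$age[i[!open]] + stats::runif(sum(!open), 0, 5)
  if (any(open)) {
    age[open] <- lt$age[k] + stats::rexp(sum(open), rate = lt$M[k])
  }
  age
}

#' Simulate a DHS-style sibling-history survey
#'
#' Respondents aged 15-49 at interview each report a sibship whose size is
#' drawn from `sibship_size_dist`; sibling lifetimes are drawn from the
#' supplied life table.  The output mimics the survey-file pathology in
#' which deceased siblings' birth and death dates are missing and must be
#' imputed from integer `age_at_death`, `years_since_death` and the
#' interview date.
#'
#' @param n_respondents Number of respondents.
#' @param lifetable A `life_table` from which sibling ages at death are
#'   drawn.
#' @param interview_date Decimal year of the interview.
#' @param sibship_size_dist Probability vector over sibship sizes 1..10
#'   (siblings per respondent).
#' @param seed RNG seed.
#' @param weight_missing_frac Fraction of respondents whose sampling weight
#'   is blanked (to emulate the missing-weight pathology).
#' @param blank_dates Blank the date columns (default TRUE, the DHS-file
#'   pathology); when FALSE exact decimal dates are kept.
#' @return A data.frame in the sibling CSV dialect:
#'   `respondent_id, weight, sib_sex, alive, current_age, age_at_death,
#'   years_since_death, birth_date, death_date, interview_date`, with the
#'   exact simulated dates attached as attribute `"truth"`.
#' @export
make_sibling_survey <- function(n_respondents, lifetable, interview_date,
                                sibship_size_dist = NULL, seed = 1,
                                weight_missing_frac = 0, blank_dates = TRUE) {
  stopifnot(inherits(lifetable, "life_table"))
  if (is.null(sibship_size_dist)) {
    sibship_size_dist <- stats::dpois(1:10, 3.5)
    sibship_size_dist <- sibship_size_dist / sum(sibship_size_dist)
  }
  if (length(sibship_size_dist) != 10L) {
    stopf("sibship_size_dist must give probabilities for sizes 1..10")
  }
  with_seed(seed, {
    sizes <- sample.int(10L, n_respondents, replace = TRUE,
                        prob = sibship_size_dist)
    rid <- rep(seq_len(n_respondents), sizes)
    n <- length(rid)
    resp_birth <- interview_date - stats::runif(n_respondents, 15, 50)
    birth <- resp_birth[rid] + stats::runif(n, -10, 10)
    sex <- ifelse(stats::runif(n) < 0.512, "male", "female")
    death_age <- draw_death_age(lifetable, n)
    death_date <- birth + death_age
    dead <- death_date < interview_date
    weight <- rep(1, n_respondents)
    if (weight_missing_frac > 0) {
      miss <- stats::runif(n_respondents) < weight_missing_frac
      weight[miss] <- NA_real_
    }
    out <- data.frame(
      respondent_id = rid,
      weight = weight[rid],
      sib_sex = sex,
      alive = !dead,
      current_age = ifelse(dead, NA_real_, floor(interview_date - birth)),
      age_at_death = ifelse(dead, floor(death_age), NA_real_),
      years_since_death = ifelse(dead, floor(interview_date - death_date),
                                 NA_real_),
      birth_date = if (blank_dates) NA_real_ else birth,
      death_date = if (blank_dates) NA_real_ else
        ifelse(dead, death_date, NA_real_),
      interview_date = interview_date)
    attr(out, "truth") <- data.frame(birth = birth,
                                     death = ifelse(dead, death_date, NA_real_))
    out
  })
}

#' Simulate a household survey with a recent-deaths module
#'
#' Household members are exposed to the piecewise-constant hazard of
#' `schedule` over the `window` years before `survey_date`; deaths are
#' simulated exactly (competing segment-wise exponential times as members
#' age across five-year groups).
#'
#' @param n_households Number of households.
#' @param schedule A [rate_schedule()] (applied to both sexes).
#' @param survey_date Decimal year of the survey.
#' @param window Lookback window in years (default 5).
#' @param mean_size Mean household size (sizes are `1 + Poisson(mean_size - 1)`).
#' @param max_entry_age Member ages at the start of the window are uniform
#'   on (0, `max_entry_age`).
#' @param seed RNG seed.
#' @return A data.frame in the household CSV dialect:
#'   `household_id, weight, sex, age, died, death_date, survey_date`
#'   (`age` is exact age at survey for survivors, at death for the dead).
#' @export
make_household_survey <- function(n_households, schedule, survey_date,
                                  window = 5, mean_size = 4,
                                  max_entry_age = 90, seed = 1) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (window <= 0) stopf("window must be positive")
  grid <- schedule$grid
  M <- schedule$M
  cell_of <- function(a) pmin(findInterval(a, ages(grid)), n_intervals(grid))
  with_seed(seed, {
    sizes <- 1L + stats::rpois(n_households, max(mean_size - 1, 0))
    hid <- rep(seq_len(n_households), sizes)
    n <- length(hid)
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    age0 <- stats::runif(n, 0, max_entry_age)

    # segment-wise exponential death times along the ageing trajectory
    alive <- rep(TRUE, n)
    a <- age0
    left <- rep(window, n)
    t_death <- rep(NA_real_, n)
    while (any(alive & left > 1e-12)) {
      act <- which(alive & left > 1e-12)
      seg <- pmin(ifelse(a[act] >= grid$open_age, left[act],
                         5 * floor(a[act] / 5) + 5 - a[act]), left[act])
      h <- M[cell_of(a[act])]
      draw <- ifelse(h > 0, stats::rexp(length(act)) / pmax(h, 1e-300), Inf)
      died_now <- draw < seg
      idx <- act[died_now]
      t_death[idx] <- (window - left[idx]) + draw[died_now]
      alive[idx] <- FALSE
      a[act] <- a[act] + seg
      left[act] <- left[act] - seg
    }
    died <- !alive
    start <- survey_date - window
    data.frame(
      household_id = hid,
      weight = 1,
      sex = sex,
      age = ifelse(died, age0 + t_death, age0 + window),
      died = died,
      death_date = ifelse(died, start + t_death, NA_real_),
      survey_date = survey_date)
  })
}
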