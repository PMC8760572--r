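#' Impute missing sibling dates from ages and years-since-death
#'
#' Survey files often blank deceased siblings' birth and death dates, leaving
#' only integer `age_at_death`, `years_since_death` and the interview date.
#' This reconstructs decimal dates with the midpoint (+0.5) convention for
#' integer-truncated values:
#' `death_date = interview_date - (years_since_death + 0.5)`,
#' `birth_date = death_date - (age_at_death + 0.5)` for the dead and
#' `birth_date = interview_date - (current_age + 0.5)` for the living.
#' Explicit dates already present are never overwritten.  Dead siblings
#' lacking both dates and the (age, years-since) pair are unusable: they are
#' dropped with a message, and the count is attached as attribute
#' `"n_unusable"`.
#'
#' @param records A data.frame in the sibling CSV dialect (see
#'   [make_sibling_survey()]).
#' @return The usable records with `birth_date` and `death_date` filled.
#' @export
impute_sibling_dates <- function(records) {
  need <- c("alive", "current_age", "age_at_death", "years_since_death",
            "birth_date", "death_date", "interview_date")
  if (!all(need %in% names(records))) {
    stopf("records must have columns %s", paste(need, collapse = ", "))
  }
  if (anyNA(records$interview_date)) stopf("interview_date must be present")
  r <- records
  dead <- !r$alive

  # dead: a death date must be explicit or derivable from years_since_death,
  # and a birth date explicit or derivable from age_at_death; living: a birth
  # date explicit or derivable from current_age
  unusable <- (dead & ((is.na(r$death_date) & is.na(r$years_since_death)) |
                         (is.na(r$birth_date) & is.na(r$age_at_death)))) |
    (!dead & is.na(r$birth_date) & is.na(r$current_age))
  n_bad <- sum(unusable)
  if (n_bad > 0) {
    message(sprintf("dropping %d unusable sibling record(s) lacking both dates and age information", n_bad))
    r <- r[!unusable, , drop = FALSE]
    dead <- !r$alive
  }

  fill_dd <- dead & is.na(r$death_date)
  r$death_date[fill_dd] <- r$interview_date[fill_dd] -
    (r$years_since_death[fill_dd] + 0.5)
  fill_bd_dead <- dead & is.na(r$birth_date)
  r$birth_date[fill_bd_dead] <- r$death_date[fill_bd_dead] -
    (r$age_at_death[fill_bd_dead] + 0.5)
  fill_bd_live <- !dead & is.na(r$birth_date)
  r$birth_date[fill_bd_live] <- r$interview_date[fill_bd_live] -
    (r$current_age[fill_bd_live] + 0.5)

  attr(r, "n_unusable") <- n_bad
  r
}

# split person-time between exact ages (entry, exit) across the age cells
# delimited by `breaks` (last break may be Inf); returns an n x (length(breaks)-1)
# matrix of years
split_age_exposure <- function(entry, exit, breaks) {
  ncell <- length(breaks) - 1L
  out <- matrix(0, length(entry), ncell)
  for (j in seq_len(ncell)) {
    out[, j] <- pmax(0, pmin(exit, breaks[j + 1L]) - pmax(entry, breaks[j]))
  }
  out
}

#' Weighted person-years and deaths from sibling histories
#'
#' Each sibling contributes respondent-weighted time at risk from
#' `max(birth, period start)` to `min(death or interview, period end)`,
#' split exactly across five-year age cells as age advances; a death whose
#' date falls inside the period and whose exact age at death falls in a cell
#' adds the respondent weight to that cell's death count.  Periods are
#' half-open `[start, end)`.
#'
#' @param records Date-complete sibling records (run
#'   [impute_sibling_dates()] first); must carry a non-missing `weight`
#'   column (screen with [screen_survey_weights()] upstream).
#' @param period Length-2 numeric `c(start, end)` in decimal years.
#' @param age_range Length-2 `c(low, high)`; default `c(15, 50)`, the range
#'   over which sibling reports are considered reliable.
#' @param sex Optional filter on `sib_sex` (`"female"` or `"male"`).
#' @return An object of class `exposure_table`: data.frame columns
#'   `age_start, person_years, deaths`, with per-respondent exposure and
#'   death matrices attached for bootstrap resampling.
#' @export
sibling_exposure <- function(records, period, age_range = c(15, 50),
                             sex = NULL) {
  if (period[2] <= period[1]) stopf("period end must exceed period start")
  r <- records
  if (!is.null(sex)) r <- r[r$sib_sex == sex, , drop = FALSE]
  if (anyNA(r$weight)) stopf("missing respondent weights: screen the survey first")
  starts <- seq(age_range[1], age_range[2] - 5, by = 5)
  breaks <- c(starts, age_range[2])
  if (nrow(r) == 0L) {
    out <- data.frame(age_start = starts, person_years = 0, deaths = 0)
    class(out) <- c("exposure_table", "data.frame")
    attr(out, "period") <- period
    return(out)
  }
  if (anyNA(r$birth_date)) stopf("records must be date-complete; run impute_sibling_dates()")

  end_obs <- ifelse(r$alive, r$interview_date, r$death_date)
  entry_t <- pmax(r$birth_date, period[1])
  exit_t <- pmin(end_obs, r$interview_date, period[2])
  entry_age <- entry_t - r$birth_date
  exit_age <- pmax(exit_t - r$birth_date, entry_age)
  expo <- split_age_exposure(entry_age, exit_age, breaks) * r$weight

  death_age <- ifelse(r$alive, NA_real_, r$death_date - r$birth_date)
  in_period <- !r$alive & r$death_date >= period[1] & r$death_date < period[2]
  dmat <- matrix(0, nrow(r), length(starts))
  for (j in seq_along(starts)) {
    hit <- in_period & death_age >= breaks[j] & death_age < breaks[j + 1L]
    dmat[hit, j] <- r$weight[hit]
  }

  # collapse to respondent level for bootstrap resampling
  rid <- factor(r$respondent_id)
  expo_by_resp <- rowsum(expo, rid)
  deaths_by_resp <- rowsum(dmat, rid)

  out <- data.frame(age_start = starts,
                    person_years = colSums(expo),
                    deaths = colSums(dmat))
  class(out) <- c("exposure_table", "data.frame")
  attr(out, "period") <- period
  attr(out, "sex") <- sex
  attr(out, "by_respondent") <- list(py = expo_by_resp,
                                     deaths = deaths_by_resp)
  out
}

#' Direct 35q15 from a sibling exposure table
#'
#' Cell rates `M = deaths / person_years` are converted to probabilities via
#' [rate_to_prob()] (n = 5, a = 2.5) and chained:
#' `35q15 = 1 - prod(1 - q)`.  Uncertainty comes from a respondent-level
#' bootstrap (resampling respondents with replacement, default 200
#' replicates) using the per-respondent matrices carried by the exposure
#' table.
#'
#' @param exposure An `exposure_table` from [sibling_exposure()] covering
#'   the seven groups 15-49.
#' @param n_boot Bootstrap replicates (default 200); 0 skips the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `direct_estimate`: `estimate`, `ci`
#'   (percentile bounds, NULL when not bootstrapped), `boot` (replicate
#'   values), `n_boot`, `seed`.
#' @export
direct_35q15 <- function(exposure, n_boot = 200, seed = 1, conf = 0.95) {
  stopifnot(inherits(exposure, "exposure_table"))
  zero <- exposure$person_years <= 0
  if (any(zero)) {
    stopf("zero exposure in age cell(s) %s: widen the period or pool surveys",
          paste(exposure$age_start[zero], collapse = ", "))
  }
  est_from <- function(py, deaths) {
    q <- rate_to_prob(deaths / py, n = 5, a = 2.5)
    1 - prod(1 - q)
  }
  est <- est_from(exposure$person_years, exposure$deaths)

  ci <- NULL
  boot <- NULL
  br <- attr(exposure, "by_respondent")
  if (n_boot > 0) {
    if (is.null(br)) {
      stopf("exposure table carries no per-respondent data: cannot bootstrap")
    }
    m <- nrow(br$py)
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      counts <- tabulate(sample.int(m, m, replace = TRUE), nbins = m)
      py <- colSums(br$py * counts)
      de <- colSums(br$deaths * counts)
      if (any(py <= 0)) return(NA_real_)
      est_from(py, de)
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
  }
  structure(list(estimate = est, ci = ci, boot = boot, n_boot = n_boot,
                 seed = seed, conf = conf),
            class = "direct_estimate")
}

#' @export
print.direct_estimate <- function(x, ...) {
  if (is.null(x$ci)) {
    cat(sprintf("35q15 = %.4f (no bootstrap)\n", x$estimate))
  } else {
    cat(sprintf("35q15 = %.4f (%.0f%% CI %.4f-%.4f, %d bootstrap replicates)\n",
                x$estimate, 100 * x$conf, x$ci[1], x$ci[2], x$n_boot))
  }
  invisible(x)
}

#' Age-sex death rates from a household recent-deaths module
#'
#' Tabulates weighted deaths and exact person-years by sex and five-year age
#' group over the half-open window `[survey_date - window, survey_date)`,
#' and summarises each sex with the downstream life-table measures.
#' Survivors contribute from `max(0, age - window)` to their age at survey;
#' the dead contribute up to their age at death.
#'
#' @param records A data.frame in the household CSV dialect (see
#'   [make_household_survey()]).
#' @param survey_date Decimal year of the survey reference date.
#' @param window_years Lookback window in years (default 5).
#' @param grid Tabulation grid (default 0-4 ... 75-79 plus 80+).
#' @param radix Life-table radix.
#' @return An object of class `household_estimates`: per-sex list of
#'   `rates` ([rate_schedule()]), `life_table` (NULL when the open-interval
#'   rate is zero and the table cannot be closed), `q1550`, `e15`; plus the
#'   mid-period label `survey_date - window/2` and, when both sexes are
#'   present with closable tables, the female-male `e15_gap`.
#' @export
household_rates <- function(records, survey_date, window_years = 5,
                            grid = age_grid(seq(0, 75, 5), 80), radix = 1e5) {
  if (window_years <= 0) stopf("window must be positive")
  start <- survey_date - window_years
  r <- records
  if (any(!is.na(r$death_date) & (r$death_date < start | r$death_date >= survey_date))) {
    stopf("death dates outside the lookback window [%s, %s)", start, survey_date)
  }
  breaks <- c(ages(grid), Inf)
  per_sex <- lapply(c(female = "female", male = "male"), function(sx) {
    s <- r[r$sex == sx, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    exit_age <- s$age
    time_in <- ifelse(s$died, s$death_date - start, window_years)
    entry_age <- pmax(0, exit_age - time_in)
    expo <- split_age_exposure(entry_age, exit_age, breaks) * s$weight
    py <- colSums(expo)
    cell <- pmin(findInterval(exit_age, ages(grid)), n_intervals(grid))
    deaths <- vapply(seq_len(n_intervals(grid)), function(j) {
      sum(s$weight[s$died & cell == j])
    }, numeric(1))
    M <- ifelse(py > 0, deaths / py, 0)
    rates <- rate_schedule(grid, M, sex = sx)
    lt <- if (M[n_intervals(grid)] > 0) build_life_table(rates, radix) else NULL
    list(rates = rates, py = py, deaths = deaths, life_table = lt,
         q1550 = if (!is.null(lt)) prob_15_50(lt) else {
           q <- rate_to_prob(M[ages(grid) >= 15 & ages(grid) < 50], 5, 2.5)
           1 - prod(1 - q)
         },
         e15 = if (!is.null(lt)) lt$e[match(15, lt$age)] else NA_real_)
  })
  per_sex <- Filter(Negate(is.null), per_sex)
  gap <- if (all(c("female", "male") %in% names(per_sex)) &&
             !is.null(per_sex$female$life_table) &&
             !is.null(per_sex$male$life_table)) {
    sexgap_e15(per_sex$female$life_table, per_sex$male$life_table)
  } else NA_real_
  structure(list(by_sex = per_sex, mid_period = survey_date - window_years / 2,
                 window = c(start, survey_date), e15_gap = gap),
            class = "household_estimates")
}

#' @export
print.household_estimates <- function(x, ...) {
  cat(sprintf("<household_estimates> window [%.1f, %.1f), mid-period %.1f\n",
              x$window[1], x$window[2], x$mid_period))
  for (sx in names(x$by_sex)) {
    cat(sprintf("  %s: 35q15 = %.4f, e15 = %s\n", sx, x$by_sex[[sx]]$q1550,
                ifelse(is.na(x$by_sex[[sx]]$e15), "NA",
                       sprintf("%.2f", x$by_sex[[sx]]$e15))))
  }
  if (!is.na(x$e15_gap)) cat(sprintf("  e15 gap (F-M) = %.2f years\n", x$e15_gap))
  invisible(x)
}

#' Screen a survey's sampling-weight column
#'
#' Computes the fraction of missing weights and issues a usable/dropped
#' verdict: the survey is dropped when the missing fraction strictly exceeds
#' the threshold (a file exactly at the threshold is retained).
#'
#' @param survey_table A data.frame.
#' @param weight_col Name of the weight column (default `"weight"`).
#' @param threshold Maximum tolerable missing fraction (default 0.5).
#' @return An object of class `weight_screen`: `usable`,
#'   `missing_fraction`, `threshold`, `n`.
#' @export
screen_survey_weights <- function(survey_table, weight_col = "weight",
                                  threshold = 0.5) {
  if (!weight_col %in% names(survey_table)) {
    stopf("no column '%s' in survey table", weight_col)
  }
  w <- survey_table[[weight_col]]
  frac <- if (length(w)) mean(is.na(w)) else 1
  usable <- frac <= threshold
  message(sprintf("weight column '%s': %.1f%% missing -> %s", weight_col,
                  100 * frac, if (usable) "usable" else "dropped"))
  structure(list(usable = usable, missing_fraction = frac,
                 threshold = threshold, n = length(w)),
            class = "weight_screen")
}

#' @export
print.weight_screen <- function(x, ...) {
  cat(sprintf("<weight_screen> %.1f%% of %d weights missing (threshold %.0f%%): %s\n",
              100 * x$missing_fraction, x$n, 100 * x$threshold,
              if (x$usable) "usable" else "dropped"))
  invisible(x)
}
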