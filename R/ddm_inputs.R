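#' Two dated census count vectors for one sex
#'
#' @param grid An [age_grid()] shared by both censuses.
#' @param sex `"female"`, `"male"` or `"total"`.
#' @param date1,date2 Census reference dates as decimal years; the
#'   intercensal length `t = date2 - date1` must lie in (1, 30).
#' @param N1,N2 Population counts per interval (closed groups then open), all
#'   non-negative.
#' @return An object of class `census_pair`.
#' @export
census_pair <- function(grid, sex, date1, date2, N1, N2) {
  stopifnot(inherits(grid, "age_grid"))
  k <- n_intervals(grid)
  t <- date2 - date1
  if (!(t > 1 && t < 30)) stopf("intercensal length must be in (1, 30), got %s", t)
  if (length(N1) != k || length(N2) != k) stopf("N1 and N2 must have %d values", k)
  if (any(N1 < 0) || any(N2 < 0)) stopf("census counts must be non-negative")
  structure(list(grid = grid, sex = sex, date1 = date1, date2 = date2,
                 N1 = as.numeric(N1), N2 = as.numeric(N2), t = t),
            class = "census_pair")
}

#' Registered intercensal deaths by age for one sex
#'
#' @param grid An [age_grid()].
#' @param sex `"female"`, `"male"` or `"total"`.
#' @param period_start,period_end Decimal years delimiting the registration
#'   period; should match the census dates of the paired [census_pair()].
#' @param deaths Registered death counts per interval over the full period,
#'   all non-negative.
#' @return An object of class `death_series`.
#' @export
death_series <- function(grid, sex, period_start, period_end, deaths) {
  stopifnot(inherits(grid, "age_grid"))
  if (period_end <= period_start) stopf("period_end must exceed period_start")
  k <- n_intervals(grid)
  if (length(deaths) != k) stopf("deaths must have %d values", k)
  if (any(deaths < 0)) stopf("death counts must be non-negative")
  structure(list(grid = grid, sex = sex, period_start = period_start,
                 period_end = period_end, deaths = as.numeric(deaths)),
            class = "death_series")
}

#' Intercensal quantities feeding the death distribution methods
#'
#' Computes, for every interval start age x of the grid, the open-ended
#' cumulations and rates that the GGB and SEG methods work with:
#' \itemize{
#'   \item `r_plus`: growth rate of the population aged x and over,
#'     `log(N2(x+)/N1(x+)) / t`;
#'   \item `r_group`: growth rate of each five-year group;
#'   \item `PY_plus`: person-years lived above x over the intercensal period,
#'     `t * sqrt(N1(x+) * N2(x+))`;
#'   \item `entry_rate`: annual rate of attaining exact age x per person-year
#'     above x.  The annual number of people turning x is estimated by the
#'     cohort-straddling geometric mean `sqrt(N1[x-5,x) * N2[x,x+5)) / 5`,
#'     which cancels the average population growth between the censuses;
#'   \item `death_rate`: registered deaths above x per person-year above x.
#' }
#' `entry_rate` is undefined (NA) at the lowest grid age, where no group
#' below x exists.
#'
#' @param cp A [census_pair()].
#' @param ds A [death_series()] on the same grid, for the same sex and period.
#' @param min_age Ages at and above `min_age` must have positive cumulated
#'   counts in both censuses (default 15, the minimum adult age of the
#'   methods).
#' @return An object of class `intercensal_inputs`: a list with the grid,
#'   `t`, and per-age vectors described above, indexed by `age`.
#' @export
intercensal_inputs <- function(cp, ds, min_age = 15) {
  stopifnot(inherits(cp, "census_pair"), inherits(ds, "death_series"))
  if (!same_grid(cp$grid, ds$grid)) stopf("census pair and deaths use different grids")
  grid <- cp$grid
  x <- ages(grid)
  t <- cp$t

  N1p <- rev(cumsum(rev(cp$N1)))   # N1(x+), open interval inclusive
  N2p <- rev(cumsum(rev(cp$N2)))
  Dp <- rev(cumsum(rev(ds$deaths)))
  bad <- x >= min_age & (N1p <= 0 | N2p <= 0)
  if (any(bad)) {
    stopf("zero cumulated population above age %d", x[which(bad)[1L]])
  }

  r_plus <- ifelse(N1p > 0 & N2p > 0, log(N2p / N1p) / t, NA_real_)
  r_group <- ifelse(cp$N1 > 0 & cp$N2 > 0, log(cp$N2 / cp$N1) / t, NA_real_)
  PY_plus <- t * sqrt(N1p * N2p)

  # annual number attaining exact age x: straddle the age with census-1 group
  # [x-5, x) and census-2 group [x, x+5)
  turning <- c(NA_real_, sqrt(cp$N1[-length(cp$N1)] * cp$N2[-1L]) / 5)
  entry_rate <- (t * turning) / PY_plus
  death_rate <- Dp / PY_plus

  structure(list(grid = grid, t = t, age = x,
                 N1_plus = N1p, N2_plus = N2p, D_plus = Dp,
                 r_plus = r_plus, r_group = r_group, PY_plus = PY_plus,
                 entry_rate = entry_rate, death_rate = death_rate),
            class = "intercensal_inputs")
}

#' Read census counts from CSV
#'
#' Expects columns `sex, age_start, open, count, date`; `open` is 0/1 marking
#' the terminal interval.  Two distinct dates must be present per sex; the
#' earlier is census 1.
#'
#' @param path CSV file path.
#' @param sex Which sex to extract.
#' @return A [census_pair()].
#' @export
read_census_csv <- function(path, sex) {
  d <- utils::read.csv(path)
  need <- c("sex", "age_start", "open", "count", "date")
  if (!all(need %in% names(d))) stopf("census CSV must have columns %s",
                                      paste(need, collapse = ", "))
  d <- d[d$sex == sex, ]
  if (!nrow(d)) stopf("no census rows for sex '%s'", sex)
  dates <- sort(unique(d$date))
  if (length(dates) != 2L) stopf("census CSV must contain exactly two dates per sex")
  d1 <- d[d$date == dates[1L], ]
  d2 <- d[d$date == dates[2L], ]
  d1 <- d1[order(d1$age_start), ]
  d2 <- d2[order(d2$age_start), ]
  if (!identical(d1$age_start, d2$age_start)) stopf("census age grids differ between dates")
  grid <- age_grid(d1$age_start[d1$open == 0], open_age = d1$age_start[d1$open == 1])
  census_pair(grid, sex, dates[1L], dates[2L], d1$count, d2$count)
}

#' Read registered intercensal deaths from CSV
#'
#' Expects columns `sex, age_start, open, deaths, period_start, period_end`.
#'
#' @param path CSV file path.
#' @param sex Which sex to extract.
#' @return A [death_series()].
#' @export
read_deaths_csv <- function(path, sex) {
  d <- utils::read.csv(path)
  need <- c("sex", "age_start", "open", "deaths", "period_start", "period_end")
  if (!all(need %in% names(d))) stopf("deaths CSV must have columns %s",
                                      paste(need, collapse = ", "))
  d <- d[d$sex == sex, ]
  if (!nrow(d)) stopf("no death rows for sex '%s'", sex)
  d <- d[order(d$age_start), ]
  grid <- age_grid(d$age_start[d$open == 0], open_age = d$age_start[d$open == 1])
  death_series(grid, sex, d$period_start[1L], d$period_end[1L], d$deaths)
}

#' Write a census pair and death series to the package CSV dialects
#'
#' @param cp A [census_pair()].
#' @param ds A [death_series()].
#' @param census_path,deaths_path Output file paths.
#' @param append Append to existing files (for writing both sexes).
#' @export
write_ddm_csv <- function(cp, ds, census_path, deaths_path, append = FALSE) {
  k <- n_intervals(cp$grid)
  open <- c(rep(0L, k - 1L), 1L)
  cens <- rbind(
    data.frame(sex = cp$sex, age_start = ages(cp$grid), open = open,
               count = cp$N1, date = cp$date1),
    data.frame(sex = cp$sex, age_start = ages(cp$grid), open = open,
               count = cp$N2, date = cp$date2))
  dths <- data.frame(sex = ds$sex, age_start = ages(ds$grid), open = open,
                     deaths = ds$deaths, period_start = ds$period_start,
                     period_end = ds$period_end)
  utils::write.table(cens, census_path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  utils::write.table(dths, deaths_path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  invisible(NULL)
}
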