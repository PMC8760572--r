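#' Compare two annual death-registration series
#'
#' Joins two registry series on (year, sex) and computes the percent
#' difference `100 * (count_b / count_a - 1)` — e.g. how many more deaths a
#' civil registry (series b) records than a health-ministry source
#' (series a).  Display values are rounded half-up to one decimal; full
#' precision is kept in `pct_diff`.
#'
#' @param series_a,series_b Data.frames with columns `year`, `sex`,
#'   `deaths`; keys must match one-to-one.
#' @return A data.frame `year, sex, count_a, count_b, pct_diff,
#'   pct_diff_display, undefined`; rows with `count_a == 0` are flagged
#'   undefined with NA percent difference.
#' @export
compare_registries <- function(series_a, series_b) {
  need <- c("year", "sex", "deaths")
  if (!all(need %in% names(series_a)) || !all(need %in% names(series_b))) {
    stopf("both series need columns %s", paste(need, collapse = ", "))
  }
  m <- merge(series_a[need], series_b[need], by = c("year", "sex"),
             suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(series_a) || nrow(m) != nrow(series_b)) {
    stopf("series do not share identical (year, sex) keys")
  }
  if (any(m$deaths_a < 0) || any(m$deaths_b < 0)) stopf("counts must be non-negative")
  undef <- m$deaths_a == 0
  pct <- ifelse(undef, NA_real_, 100 * (m$deaths_b / m$deaths_a - 1))
  out <- data.frame(year = m$year, sex = m$sex,
                    count_a = m$deaths_a, count_b = m$deaths_b,
                    pct_diff = pct,
                    pct_diff_display = round_half_up(pct, 1),
                    undefined = undef)
  out[order(out$year, out$sex), ]
}

#' Range of registry percent differences over years
#'
#' @param comparison Output of [compare_registries()].
#' @param years Optional year filter.
#' @param sex Optional sex filter.
#' @return Named vector `c(min, max)` of the full-precision differences.
#' @export
registry_diff_range <- function(comparison, years = NULL, sex = NULL) {
  d <- comparison
  if (!is.null(years)) d <- d[d$year %in% years, ]
  if (!is.null(sex)) d <- d[d$sex %in% sex, ]
  d <- d[!d$undefined, ]
  if (!nrow(d)) stopf("no rows selected")
  c(min = min(d$pct_diff), max = max(d$pct_diff))
}

#' Published annual deaths from the two Peruvian registries, 2005-2019
#'
#' The published total registered deaths by year and sex from the Ministry
#' of Health (MINSA; the 2019 values are the SINADEF online records) and the
#' civil registry (RENIEC), shipped with the package as a plain CSV.
#'
#' @return A data.frame `year, sex, minsa, reniec`.
#' @export
peru_registry_deaths <- function() {
  path <- system.file("extdata", "peru_registry_deaths_2005_2019.csv",
                      package = "crvsddm", mustWork = TRUE)
  utils::read.csv(path)
}

#' Format a completeness estimate as "mean (min-max)"
#'
#' The "mean value (sensitivity analysis interval)" display used in
#' completeness tables: two decimals, en-dash separator.
#'
#' @param mean,min,max Numbers with `min <= mean <= max`.
#' @return A string like `"0.80 (0.76–0.85)"`.
#' @export
format_estimate <- function(mean, min, max) {
  if (!(min <= mean + 1e-12 && mean <= max + 1e-12)) {
    stopf("ordering violated: need min <= mean <= max, got (%s, %s, %s)",
          mean, min, max)
  }
  sprintf("%.2f (%.2f–%.2f)", round_half_up(mean, 2),
          round_half_up(min, 2), round_half_up(max, 2))
}

#' Run the end-to-end completeness and adult-mortality pipeline
#'
#' Orchestrates the full analysis for a pair of census/death CSV files:
#' per-sex age-trim sweeps of the requested death distribution methods,
#' completeness-adjusted rates at the minimum, mean and maximum of each
#' sweep, adjusted life tables, 35q15 and the female-male e15 gap, optional
#' sibling-history and household-death estimates, and CSV/JSON outputs with
#' provenance metadata.  Running twice with the same config produces
#' identical outputs.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{census_file, deaths_file}{input CSVs (see [read_census_csv()],
#'       [read_deaths_csv()]); required.}
#'     \item{out_dir}{output directory; required, created if absent.}
#'     \item{sexes}{default `c("female", "male")`.}
#'     \item{methods}{subset of `c("ggbseg", "seg")`; default both.}
#'     \item{min_groups, low, high_end}{trim-sweep parameters (8, 15, 80).}
#'     \item{fit}{GGB regression flavour, `"ols"` or `"orthogonal"`.}
#'     \item{radix}{life-table radix (1e5).}
#'     \item{sibling_file, sibling_period}{optional sibling CSV and
#'       `c(start, end)` period for direct estimation.}
#'     \item{household_file, household_survey_date, household_window}{optional
#'       household CSV and its reference date / lookback window.}
#'     \item{n_boot, seed}{bootstrap replicates (200) and seed (1).}
#'   }
#' @return (Invisibly) a list with `completeness`, `summary`, `adjusted`
#'   (per method/statistic life-table measures), `sexgap`, `sibling`,
#'   `household` and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  req <- c("census_file", "deaths_file", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stopf("config lacks required element(s): %s",
                          paste(miss, collapse = ", "))
  for (f in c("census_file", "deaths_file", "sibling_file", "household_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stopf("config file '%s' does not exist: %s", f, config[[f]])
    }
  }
  sexes <- config$sexes %||% c("female", "male")
  methods <- config$methods %||% c("ggbseg", "seg")
  min_groups <- config$min_groups %||% 8
  low <- config$low %||% 15
  high_end <- config$high_end %||% 80
  fit <- config$fit %||% "ols"
  radix <- config$radix %||% 1e5
  n_boot <- config$n_boot %||% 200
  seed <- config$seed %||% 1
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  per_window <- list(); summary_rows <- list(); adjusted_rows <- list()
  tables <- list()
  for (sx in sexes) {
    cp <- read_census_csv(config$census_file, sx)
    ds <- read_deaths_csv(config$deaths_file, sx)
    for (mth in methods) {
      ce <- if (mth == "ggbseg") {
        trim_sweep(cp, ds, "ggbseg", min_groups, low, high_end, fit = fit)
      } else {
        trim_sweep(cp, ds, mth, min_groups, low, high_end)
      }
      pw <- ce$per_window
      per_window[[paste(mth, sx)]] <- data.frame(
        method = mth, sex = sx, window_low = pw$low, window_high = pw$high,
        C = pw$C)
      summary_rows[[paste(mth, sx)]] <- data.frame(
        method = mth, sex = sx, mean = ce$mean, min = ce$min, max = ce$max,
        display = format_estimate(ce$mean, ce$min, ce$max))
      for (stat in c("min", "mean", "max")) {
        C <- ce[[stat]]
        lt <- build_life_table(adjust_rates(ds, cp, C, sex = sx), radix)
        tables[[paste(mth, stat, sx)]] <- lt
        adjusted_rows[[paste(mth, stat, sx)]] <- data.frame(
          method = mth, stat = stat, sex = sx, C = C,
          q1550 = prob_15_50(lt), e15 = lt$e[match(15, lt$age)])
      }
    }
  }
  completeness <- do.call(rbind, per_window)
  summary <- do.call(rbind, summary_rows)
  adjusted <- do.call(rbind, adjusted_rows)
  rownames(completeness) <- rownames(summary) <- rownames(adjusted) <- NULL

  sexgap <- NULL
  if (all(c("female", "male") %in% sexes)) {
    sexgap <- do.call(rbind, lapply(methods, function(mth) {
      do.call(rbind, lapply(c("min", "mean", "max"), function(stat) {
        data.frame(method = mth, stat = stat,
                   e15_gap = sexgap_e15(tables[[paste(mth, stat, "female")]],
                                        tables[[paste(mth, stat, "male")]]))
      }))
    }))
  }

  sibling <- NULL
  if (!is.null(config$sibling_file)) {
    sib <- utils::read.csv(config$sibling_file)
    screen <- screen_survey_weights(sib)
    if (screen$usable) {
      sib <- impute_sibling_dates(sib)
      period <- config$sibling_period %||%
        (max(sib$interview_date) - c(10, 0))
      sibling <- do.call(rbind, lapply(c("female", "male"), function(sx) {
        ex <- sibling_exposure(sib, period, sex = sx)
        dq <- direct_35q15(ex, n_boot = n_boot, seed = seed)
        data.frame(sex = sx, period_start = period[1], period_end = period[2],
                   q1550 = dq$estimate,
                   ci_low = dq$ci[1] %||% NA_real_,
                   ci_high = dq$ci[2] %||% NA_real_,
                   n_unusable = attr(sib, "n_unusable") %||% 0L)
      }))
    } else {
      message("sibling survey dropped by weight screening")
      sibling <- data.frame(sex = character(), period_start = numeric(),
                            period_end = numeric(), q1550 = numeric(),
                            ci_low = numeric(), ci_high = numeric(),
                            n_unusable = integer())
    }
  }

  household <- NULL
  if (!is.null(config$household_file)) {
    hh <- utils::read.csv(config$household_file)
    hh$died <- as.logical(hh$died)
    sdate <- config$household_survey_date %||% hh$survey_date[1]
    household <- household_rates(hh, sdate,
                                 window_years = config$household_window %||% 5)
  }

  files <- character(0)
  wr <- function(d, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  files <- c(files, wr(completeness, "completeness.csv"),
             wr(summary, "completeness_summary.csv"),
             wr(adjusted, "adjusted_measures.csv"))
  if (!is.null(sexgap)) files <- c(files, wr(sexgap, "e15_sexgap.csv"))
  if (!is.null(sibling)) files <- c(files, wr(sibling, "sibling_direct.csv"))
  if (!is.null(household)) {
    hh_rows <- do.call(rbind, lapply(names(household$by_sex), function(sx) {
      data.frame(sex = sx, mid_period = household$mid_period,
                 q1550 = household$by_sex[[sx]]$q1550,
                 e15 = household$by_sex[[sx]]$e15)
    }))
    files <- c(files, wr(hh_rows, "household_direct.csv"))
  }
  meta <- list(
    package = "crvsddm",
    version = as.character(utils::packageVersion("crvsddm")),
    config = config[setdiff(names(config), "out_dir")],
    seed = seed,
    decisions = list(
      a_closed_intervals = "n/2",
      open_interval_closure = "e = 1/M(open)",
      ggb_fit = fit,
      ggbseg_adjusted_census = "census2",
      seg_open_closure = "self-consistent e(open) = C / M_obs(open)",
      date_imputation_offset = 0.5,
      windows = list(min_groups = min_groups, low = low, high_end = high_end)))
  meta_path <- file.path(config$out_dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, meta_path)

  invisible(list(completeness = completeness, summary = summary,
                 adjusted = adjusted, sexgap = sexgap, sibling = sibling,
                 household = household, files = files))
}
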