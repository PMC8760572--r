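#' Generalized growth balance (GGB) fit
#'
#' The growth balance identity links the rate of entry into the population
#' aged x and over to its growth and death rates.  With two censuses of
#' coverage k1 and k2 and registered deaths capturing a fraction C of true
#' deaths, the observed points satisfy
#'
#' \deqn{entry(x+) - r(x+) = (1/C) \cdot deathrate(x+) + \ln(k1/k2)/t,}
#'
#' so a straight-line fit over a window of cumulation ages estimates
#' completeness from the slope and relative census coverage from the
#' intercept.
#'
#' @param ii An [intercensal_inputs()] object.
#' @param window Length-2 numeric `c(low, high)`: the fit uses cumulation
#'   ages x with `low <= x <= high - 5` (i.e. the starts of the five-year
#'   groups inside `[low, high)`).
#' @param fit `"ols"` (default) for ordinary least squares or
#'   `"orthogonal"` for total least squares; the method literature uses both.
#' @return An object of class `ggb_fit`: window, slope, intercept,
#'   `C = 1/slope`, `rel_coverage = exp(intercept * t)` (the k1/k2 estimate),
#'   per-point residuals, the fitted points, and a `degenerate` flag (fewer
#'   than 3 points or non-positive slope; `C` is then NA, never clipped).
#' @export
ggb_fit <- function(ii, window, fit = c("ols", "orthogonal")) {
  stopifnot(inherits(ii, "intercensal_inputs"))
  fit <- match.arg(fit)
  use <- which(ii$age >= window[1] & ii$age <= window[2] - 5 &
                 is.finite(ii$entry_rate) & is.finite(ii$death_rate))
  xs <- ii$death_rate[use]
  ys <- ii$entry_rate[use] - ii$r_plus[use]
  out <- list(window = window, fit = fit, ages = ii$age[use],
              x = xs, y = ys, t = ii$t)
  if (length(use) < 3L) {
    out <- c(out, list(slope = NA_real_, intercept = NA_real_, C = NA_real_,
                       rel_coverage = NA_real_, residuals = NULL,
                       degenerate = TRUE, reason = "fewer than 3 points"))
    class(out) <- "ggb_fit"
    return(out)
  }
  if (fit == "ols") {
    slope <- stats::cov(xs, ys) / stats::var(xs)
  } else {
    sxx <- stats::var(xs); syy <- stats::var(ys); sxy <- stats::cov(xs, ys)
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(ys) - slope * mean(xs)
  degenerate <- !is.finite(slope) || slope <= 0
  out <- c(out, list(
    slope = slope, intercept = intercept,
    C = if (degenerate) NA_real_ else 1 / slope,
    rel_coverage = exp(intercept * ii$t),
    residuals = ys - (intercept + slope * xs),
    degenerate = degenerate,
    reason = if (degenerate) "non-positive slope" else NA_character_))
  class(out) <- "ggb_fit"
  out
}

#' @export
print.ggb_fit <- function(x, ...) {
  cat(sprintf("<ggb_fit> window [%s, %s), %d points, %s\n", x$window[1],
              x$window[2], length(x$x), x$fit))
  if (x$degenerate) {
    cat(sprintf("  degenerate fit: %s\n", x$reason))
  } else {
    cat(sprintf("  C = %.4f, k1/k2 = %.4f\n", x$C, x$rel_coverage))
  }
  invisible(x)
}

# observed open-interval death rate D*(open)/PY(open), used to seed the SEG
# closure e(open) = C / M_obs(open)
open_rate_obs <- function(cp, ds) {
  k <- n_intervals(cp$grid)
  PY_open <- cp$t * sqrt(cp$N1[k] * cp$N2[k])
  if (PY_open <= 0) stopf("zero population in the open interval")
  ds$deaths[k] / PY_open
}

#' Synthetic extinct generations (SEG) completeness estimate
#'
#' Reconstructs the number of people attaining each exact age x per year by
#' accumulating the registered deaths above x, weighted by the intercensal
#' age-specific growth rates (discrete Bennett-Horiuchi recursion):
#'
#' \deqn{\hat N(x) = \hat N(x+5) e^{5 r(x)} + \bar D(x) e^{2.5 r(x)},}
#'
#' with annualised group deaths \eqn{\bar D = D^*/t} (the deaths between
#' ages x and x+5 per calendar year).  The open interval is
#' seeded by \eqn{\hat N(A) = \bar D(A)[e^{r(A+)\hat e} - (r(A+)\hat e)^2/6]}
#' where \eqn{\hat e} is the remaining life expectancy at the open age.
#' Synthetic five-year group counts `2.5 * (N_hat(x) + N_hat(x+5))` are then
#' compared with the geometric-mean census counts: their ratio estimates
#' completeness C, aggregated over the window.
#'
#' @param ii An [intercensal_inputs()] object.
#' @param cp,ds The [census_pair()] and [death_series()] behind `ii`.
#' @param window Length-2 `c(low, high)`: ratios are aggregated over the
#'   closed groups inside `[low, high)`.
#' @param open_closure_e Optional fixed life expectancy at the open age
#'   (years).  When `NULL` (default) it is solved self-consistently: starting
#'   from the unadjusted open-interval death rate, \eqn{\hat e = C / M_{obs}}
#'   is iterated with the completeness estimate until convergence, so that
#'   the closure reflects completeness-adjusted old-age mortality.
#' @param agg `"mean"` (default) or `"median"` aggregation of the
#'   age-specific ratios over the window.
#' @return An object of class `seg_result`: window, per-group `N_hat`,
#'   `ratios`, aggregate `C`, and the closure `e_open` used.  Values of C
#'   above 1 are reported as-is, never truncated.
#' @export
seg_estimate <- function(ii, cp, ds, window, open_closure_e = NULL,
                         agg = c("mean", "median")) {
  stopifnot(inherits(ii, "intercensal_inputs"))
  agg <- match.arg(agg)
  grid <- ii$grid
  k <- n_intervals(grid)
  x <- ages(grid)
  Dbar <- ds$deaths / ii$t
  if (Dbar[k] <= 0) stopf("zero registered deaths in the open interval: SEG closure impossible")
  r_open <- ii$r_plus[k]
  M_obs <- open_rate_obs(cp, ds)
  in_win <- which(x >= window[1] & x + 5 <= window[2] & seq_len(k) < k)
  if (!length(in_win)) stopf("window [%s, %s) contains no closed groups", window[1], window[2])

  N_geo <- sqrt(cp$N1 * cp$N2)
  run_once <- function(e_open) {
    N_hat <- numeric(k)
    z <- r_open * e_open
    N_hat[k] <- Dbar[k] * (exp(z) - z^2 / 6)
    for (i in (k - 1L):1L) {
      r <- ii$r_group[i]
      N_hat[i] <- N_hat[i + 1L] * exp(5 * r) + Dbar[i] * exp(2.5 * r)
    }
    ratios <- rep(NA_real_, k)
    cl <- seq_len(k - 1L)
    ratios[cl] <- 2.5 * (N_hat[cl] + N_hat[cl + 1L]) / N_geo[cl]
    C <- if (agg == "mean") mean(ratios[in_win]) else stats::median(ratios[in_win])
    list(N_hat = N_hat, ratios = ratios, C = C)
  }

  if (!is.null(open_closure_e)) {
    e_open <- open_closure_e
    res <- run_once(e_open)
  } else {
    # self-consistent closure: e(open) = C / M_obs(open)
    e_open <- 1 / M_obs
    res <- run_once(e_open)
    for (iter in seq_len(50L)) {
      e_new <- res$C / M_obs
      res_new <- run_once(e_new)
      if (abs(res_new$C - res$C) < 1e-8) { e_open <- e_new; res <- res_new; break }
      e_open <- e_new
      res <- res_new
    }
  }
  structure(list(window = window, age = x, N_hat = res$N_hat,
                 ratios = res$ratios, C = res$C, e_open = e_open,
                 sex = cp$sex, agg = agg),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> window [%s, %s): C = %.4f (e_open = %.1f)\n",
              x$window[1], x$window[2], x$C, x$e_open))
  invisible(x)
}

#' Combined GGB-SEG completeness estimate
#'
#' Runs [ggb_fit()] on the window to estimate relative census coverage
#' k1/k2, rescales the second census onto the coverage scale of the first
#' (`N2 * k1/k2`), rebuilds the intercensal inputs, and applies
#' [seg_estimate()].  This removes the bias that differential census
#' enumeration induces in plain SEG.
#'
#' @inheritParams seg_estimate
#' @param fit Regression flavour passed to [ggb_fit()].
#' @param adjust Which census to rescale: `"census2"` (default; the first
#'   census anchors the series) or `"census1"` (divided by k1/k2 instead).
#' @return A `seg_result`, with the `ggb` fit and the coverage adjustment
#'   attached.
#' @export
ggbseg_estimate <- function(ii, cp, ds, window, open_closure_e = NULL,
                            agg = c("mean", "median"),
                            fit = c("ols", "orthogonal"),
                            adjust = c("census2", "census1")) {
  adjust <- match.arg(adjust)
  gf <- ggb_fit(ii, window, fit = match.arg(fit))
  if (gf$degenerate) {
    stopf("GGB fit on window [%s, %s) is degenerate (%s): cannot run GGB-SEG",
          window[1], window[2], gf$reason)
  }
  k1k2 <- gf$rel_coverage
  cp_adj <- if (adjust == "census2") {
    census_pair(cp$grid, cp$sex, cp$date1, cp$date2, cp$N1, cp$N2 * k1k2)
  } else {
    census_pair(cp$grid, cp$sex, cp$date1, cp$date2, cp$N1 / k1k2, cp$N2)
  }
  ii_adj <- intercensal_inputs(cp_adj, ds, min_age = min(window[1], 15))
  out <- seg_estimate(ii_adj, cp_adj, ds, window,
                      open_closure_e = open_closure_e, agg = agg)
  out$ggb <- gf
  out$adjust <- adjust
  out
}

#' Enumerate the age-trim windows of the sensitivity sweep
#'
#' All contiguous runs of at least `min_groups` five-year groups whose first
#' group starts at or above `low` and whose last group ends at or below
#' `high_end`.
#'
#' @param grid An [age_grid()] covering `[low, high_end)`.
#' @param min_groups Minimum number of adjacent groups per window (default 8).
#' @param low Lowest admissible group start (default 15).
#' @param high_end Upper bound of the highest admissible group (default 80,
#'   i.e. groups up to 75-79).
#' @return A data.frame with columns `low`, `high` (half-open window bounds)
#'   and `n_groups`.
#' @export
enumerate_trim_windows <- function(grid, min_groups = 8, low = 15,
                                   high_end = 80) {
  starts <- grid$start_ages[grid$start_ages >= low & grid$start_ages + 5 <= high_end]
  n <- length(starts)
  if (n < min_groups) stopf("no admissible window: %d groups available, %d required",
                            n, min_groups)
  out <- do.call(rbind, lapply(seq(min_groups, n), function(L) {
    i <- seq_len(n - L + 1L)
    data.frame(low = starts[i], high = starts[i + L - 1L] + 5, n_groups = L)
  }))
  rownames(out) <- NULL
  out
}

#' Age-trim sensitivity sweep of a death distribution method
#'
#' Runs GGB, SEG or combined GGB-SEG over every admissible trim window (see
#' [enumerate_trim_windows()]) and summarises the completeness estimates by
#' their mean, minimum and maximum — the "mean (sensitivity interval)"
#' presentation used for completeness tables.
#'
#' @param cp A [census_pair()].
#' @param ds A [death_series()] on the same grid.
#' @param method `"ggb"`, `"seg"` or `"ggbseg"`.
#' @param min_groups,low,high_end Window enumeration parameters; defaults
#'   8 adjacent groups between ages 15 and 80.
#' @param ... Further arguments passed to the per-window method
#'   ([ggb_fit()], [seg_estimate()] or [ggbseg_estimate()]).
#' @return An object of class `completeness_estimate`: method, sex,
#'   `mean`, `min`, `max` over windows, and `per_window` (a data.frame of
#'   window bounds and C).  Degenerate GGB windows yield NA and are excluded
#'   from the summary with a warning.
#' @export
trim_sweep <- function(cp, ds, method = c("ggbseg", "seg", "ggb"),
                       min_groups = 8, low = 15, high_end = 80, ...) {
  method <- match.arg(method)
  ii <- intercensal_inputs(cp, ds, min_age = low)
  win <- enumerate_trim_windows(cp$grid, min_groups = min_groups, low = low,
                                high_end = high_end)
  win$C <- vapply(seq_len(nrow(win)), function(i) {
    w <- c(win$low[i], win$high[i])
    switch(method,
           ggb = ggb_fit(ii, w, ...)$C,
           seg = seg_estimate(ii, cp, ds, w, ...)$C,
           ggbseg = ggbseg_estimate(ii, cp, ds, w, ...)$C)
  }, numeric(1))
  if (anyNA(win$C)) {
    warning(sprintf("%d degenerate window(s) excluded from the summary",
                    sum(is.na(win$C))))
  }
  ok <- win$C[!is.na(win$C)]
  if (!length(ok)) stopf("all windows degenerate: no completeness estimate")
  structure(list(method = method, sex = cp$sex,
                 mean = mean(ok), min = min(ok), max = max(ok),
                 per_window = win),
            class = "completeness_estimate")
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat(sprintf("<completeness_estimate> %s, %s: %s over %d windows\n",
              toupper(x$method), x$sex,
              format_estimate(x$mean, x$min, x$max), nrow(x$per_window)))
  invisible(x)
}

#' Completeness-adjusted central death rates
#'
#' Divides registered deaths by the completeness estimate and by the
#' intercensal person-years `PY(x) = t * sqrt(N1(x) * N2(x))` of each group:
#' `M(x) = D*(x) / (C * PY(x))`.
#'
#' @param ds A [death_series()].
#' @param cp The matching [census_pair()].
#' @param C Completeness in (0, Inf); 1 leaves the rates unadjusted.
#' @param sex Overrides the sex label (defaults to the census pair's).
#' @return A [rate_schedule()] on the shared grid.
#' @export
adjust_rates <- function(ds, cp, C, sex = NULL) {
  stopifnot(inherits(ds, "death_series"), inherits(cp, "census_pair"))
  if (!is.finite(C) || C <= 0) stopf("completeness C must be positive")
  if (!same_grid(cp$grid, ds$grid)) stopf("census pair and deaths use different grids")
  PY <- cp$t * sqrt(cp$N1 * cp$N2)
  if (any(PY <= 0)) stopf("zero person-years in group starting at age %s",
                          ages(cp$grid)[which(PY <= 0)[1L]])
  M <- ds$deaths / (C * PY)
  sx <- sex %||% cp$sex
  if (!sx %in% c("female", "male", "total")) sx <- "total"
  rate_schedule(cp$grid, M, sex = sx)
}
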