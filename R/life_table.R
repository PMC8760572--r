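#' Age-specific mortality rate schedule
#'
#' Bundles a vector of central death rates M(x) (deaths per person-year) on an
#' [age_grid()] together with the average-years-lived values a(x) used when
#' converting rates to probabilities.  The default a(x) = n/2 = 2.5 for closed
#' intervals is the conventional abridged-life-table choice at adult ages.
#'
#' @param grid An [age_grid()].
#' @param M Numeric vector of central death rates, one per interval (closed
#'   groups then the open interval); all must be non-negative and finite.
#' @param sex `"female"`, `"male"` or `"total"`; carried as metadata.
#' @param a Average years lived in the interval by those dying in it; one
#'   value per closed interval, each in (0, 5].  Ignored for the open interval.
#' @return An object of class `rate_schedule`.
#' @export
rate_schedule <- function(grid, M, sex = c("total", "female", "male"),
                          a = NULL) {
  sex <- match.arg(sex)
  stopifnot(inherits(grid, "age_grid"))
  k <- n_intervals(grid)
  if (length(M) != k) stopf("M must have %d values, got %d", k, length(M))
  if (any(!is.finite(M)) || any(M < 0)) stopf("M must be finite and >= 0")
  if (is.null(a)) a <- rep(2.5, k - 1L)
  if (length(a) != k - 1L) stopf("a must have one value per closed interval")
  if (any(a <= 0 | a > 5)) stopf("a must lie in (0, 5]")
  structure(list(grid = grid, sex = sex, M = as.numeric(M), a = as.numeric(a)),
            class = "rate_schedule")
}

#' Convert a central death rate to an interval death probability
#'
#' Standard abridged conversion q = n M / (1 + (n - a) M), clipped to
#' \[0, 1\].  Vectorised over `M`, `n` and `a`.
#'
#' @param M Central death rate (per person-year), >= 0.
#' @param n Interval width in years.
#' @param a Average years lived in the interval by those dying in it,
#'   in (0, n].
#' @return Death probability in \[0, 1\].
#' @examples
#' rate_to_prob(0.02, n = 5, a = 2.5)
#' @export
rate_to_prob <- function(M, n = 5, a = n / 2) {
  if (any(!is.finite(M)) || any(M < 0)) stopf("M must be finite and >= 0")
  if (any(a <= 0) || any(a > n)) stopf("a must lie in (0, n]")
  q <- n * M / (1 + (n - a) * M)
  pmin(pmax(q, 0), 1)
}

#' Build an abridged period life table from a rate schedule
#'
#' Applies the standard abridged recursion: q(x) from [rate_to_prob()],
#' survivors l(x) by attrition from the radix, deaths d(x) = l(x) q(x),
#' person-years L(x) = n l(x+n) + a(x) d(x) for closed intervals, and the
#' open interval closed by L = l / M (equivalently e(open) = 1 / M(open)).
#'
#' @param rates A [rate_schedule()].  The open-interval rate must be positive
#'   so the table can be closed.
#' @param radix Survivors at the first age of the table (default 100000).
#' @return A `life_table`: a data.frame with columns
#'   `age, n, M, a, q, l, d, L, T, e` and attributes `sex` and `grid`.
#' @export
build_life_table <- function(rates, radix = 1e5) {
  stopifnot(inherits(rates, "rate_schedule"))
  if (radix <= 0) stopf("radix must be positive")
  grid <- rates$grid
  k <- n_intervals(grid)
  M <- rates$M
  if (M[k] <= 0) stopf("open-interval rate is zero: life table cannot be closed")
  n <- c(rep(5, k - 1L), NA_real_)
  a <- c(rates$a, NA_real_)
  q <- c(rate_to_prob(M[-k], n = 5, a = rates$a), 1)
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- numeric(k)
  L[-k] <- 5 * l[-1L] + a[-k] * d[-k]   # n*l(x+n) + a*d
  L[k] <- l[k] / M[k]
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)
  out <- data.frame(age = ages(grid), n = n, M = M, a = a, q = q,
                    l = l, d = d, L = L, T = T, e = e)
  attr(out, "sex") <- rates$sex
  attr(out, "grid") <- grid
  class(out) <- c("life_table", "data.frame")
  out
}

#' Probability of dying between exact ages 15 and 50
#'
#' The adult-mortality summary 35q15 = 1 - l(50) / l(15), the probability
#' that a person alive at exact age 15 dies before exact age 50 under the
#' period's rates.
#'
#' @param lt A `life_table` from [build_life_table()]; must contain interval
#'   starts at both 15 and 50.
#' @return A probability in \[0, 1\].
#' @export
prob_15_50 <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  i15 <- match(15, lt$age)
  i50 <- match(50, lt$age)
  if (is.na(i15) || is.na(i50)) {
    stopf("life table must contain exact ages 15 and 50")
  }
  if (lt$l[i15] <= 0) return(1)
  1 - lt$l[i50] / lt$l[i15]
}

#' Female-male gap in life expectancy at age 15
#'
#' Returns e15(female) - e15(male): positive values mean a female survival
#' advantage.
#'
#' @param female,male `life_table` objects on identical grids, each
#'   containing exact age 15.
#' @return Gap in years (signed).
#' @export
sexgap_e15 <- function(female, male) {
  stopifnot(inherits(female, "life_table"), inherits(male, "life_table"))
  if (!same_grid(attr(female, "grid"), attr(male, "grid"))) {
    stopf("female and male life tables are on different age grids")
  }
  i <- match(15, female$age)
  if (is.na(i)) stopf("life tables must contain exact age 15")
  female$e[i] - male$e[i]
}

#' Write a life table to CSV
#'
#' Serialises the standard columns `age,n,M,a,q,l,d,L,T,e`.
#'
#' @param lt A `life_table`.
#' @param path Output file path.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, na = "")
  invisible(path)
}
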