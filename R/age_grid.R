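#' Five-year age grid with an open terminal interval
#'
#' An `age_grid` describes the abridged age classification used throughout the
#' package: consecutive five-year groups `[x, x+5)` followed by exactly one
#' open-ended terminal interval (e.g. 80+).  All population, death and
#' life-table vectors in the package are indexed by the starts of these
#' intervals.
#'
#' @param start_ages Integer vector of closed-interval start ages; must be
#'   strictly increasing in constant steps of 5.
#' @param open_age Start of the open terminal interval; must equal
#'   `max(start_ages) + 5`.
#' @return An object of class `age_grid` with fields `start_ages` and
#'   `open_age`.
#' @examples
#' g <- age_grid(seq(0, 75, by = 5), open_age = 80)
#' ages(g)
#' @export
age_grid <- function(start_ages, open_age) {
  start_ages <- as.integer(start_ages)
  open_age <- as.integer(open_age)
  if (length(start_ages) < 1L) stopf("age_grid needs at least one closed group")
  d <- diff(start_ages)
  if (length(d) && any(d != 5L)) {
    stopf("closed start ages must increase in constant steps of 5")
  }
  if (open_age != max(start_ages) + 5L) {
    stopf("open_age must be max(start_ages) + 5, got %d", open_age)
  }
  structure(list(start_ages = start_ages, open_age = open_age),
            class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("<age_grid> %d closed 5-year groups %d-%d, open interval %d+\n",
              length(x$start_ages), min(x$start_ages),
              max(x$start_ages) + 4L, x$open_age))
  invisible(x)
}

#' Interval start ages of a grid, including the open interval
#' @param grid An [age_grid()].
#' @return Integer vector `c(start_ages, open_age)`.
#' @export
ages <- function(grid) {
  stopifnot(inherits(grid, "age_grid"))
  c(grid$start_ages, grid$open_age)
}

# number of intervals including the open one
n_intervals <- function(grid) length(grid$start_ages) + 1L

# interval widths; the open interval is Inf
interval_widths <- function(grid) c(rep(5, length(grid$start_ages)), Inf)

# index of age x among interval starts, error when absent
age_index <- function(grid, x) {
  i <- match(x, ages(grid))
  if (is.na(i)) stopf("age %s is not an interval start of this grid", x)
  i
}

same_grid <- function(a, b) {
  identical(a$start_ages, b$start_ages) && identical(a$open_age, b$open_age)
}
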