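#' @import data.table
#' @importFrom stats as.formula binomial coef glm median pnorm poisson qlogis
#'   quantile rbinom rexp rnorm runif rpois rbeta setNames uniroot vcov
#'   plogis complete.cases
#' @importFrom utils packageVersion
NULL

# Internal date grid: integer days (R Date epoch days). All engine and
# endpoint arithmetic runs on this grid; I/O converts from/to ISO-8601.

#' Convert dates to the integer day grid
#'
#' @param x a `Date`, ISO-8601 character vector, or integer day vector.
#' @return integer days since 1970-01-01.
#' @keywords internal
as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.character(x) || is.factor(x)) return(as.integer(as.Date(as.character(x))))
  as.integer(x)
}

day_to_date <- function(x) as.Date(as.integer(x), origin = "1970-01-01")

# Fixed study constants (configurable where functions take arguments).
# "13 months" is 396 days (13 x 30.44 rounded); "6 months" is 183 days.
DAYS_13_MONTHS <- 396L
DAYS_6_MONTHS <- 183L
DAYS_PER_MONTH <- 30.44

ERA_BREAKS <- function() as_day(c("1995-01-01", "2001-01-01", "2006-01-01", "2012-01-01"))
ERA_LABELS <- c("1995-2000", "2001-2005", "2006-2011")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Number of exposed days <= x for sorted disjoint half-open intervals
# [starts_i, ends_i). Vectorised over x.
cum_exposed_days <- function(starts, ends, x) {
  if (length(starts) == 0L) return(rep(0L, length(x)))
  plen <- cumsum(ends - starts)
  idx <- findInterval(x, starts)
  out <- rep(0L, length(x))
  hit <- idx > 0L
  if (any(hit)) {
    i <- idx[hit]
    out[hit] <- plen[i] - pmax(0L, ends[i] - (x[hit] + 1L))
  }
  out
}

# Union of possibly overlapping half-open integer intervals; returns a list
# with sorted disjoint starts/ends.
union_intervals <- function(starts, ends) {
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(list(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- integer(length(starts)); out_e <- integer(length(starts))
  k <- 1L; out_s[1L] <- starts[1L]; out_e[1L] <- ends[1L]
  if (length(starts) > 1L) {
    for (i in 2L:length(starts)) {
      if (starts[i] <= out_e[k]) {
        if (ends[i] > out_e[k]) out_e[k] <- ends[i]
      } else {
        k <- k + 1L; out_s[k] <- starts[i]; out_e[k] <- ends[i]
      }
    }
  }
  list(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

# Intersection of one interval set with another (both half-open, sorted or not).
intersect_intervals <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L)
    return(list(start = integer(0), end = integer(0)))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s1)) {
    lo <- pmax(s1[i], s2); hi <- pmin(e1[i], e2)
    keep <- hi > lo
    out_s <- c(out_s, lo[keep]); out_e <- c(out_e, hi[keep])
  }
  union_intervals(out_s, out_e)
}
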