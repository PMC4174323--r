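#' Theoretical bounds of Tajima's D
#'
#' In the large-S limit D is confined to a finite interval fixed by the
#' sample size: the minimum corresponds to every segregating site being a
#' singleton, the maximum to every site at the most even frequency
#' attainable.  The maximal mean pairwise diversity per segregating site
#' is `n/(2(n-1))` for even n and `(n+1)/(2n)` for odd n (the derived
#' count sits at `floor(n/2)`).
#'
#' @param n sample size (number of sequences fed to the limit, >= 4).
#' @return named numeric vector `c(d_min, d_max)`.
#' @export
d_bounds <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n)) {
    stop("`n` must be a single integer >= 4")
  }
  k <- tajima_constants(n)
  pi_max <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  d_min <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  d_max <- (pi_max - 1 / k$a1) / sqrt(k$e2)
  c(d_min = d_min, d_max = d_max)
}

#' Neutral range of Tajima's D (beta approximation)
#'
#' Under neutrality D is approximated by a beta density rescaled to its
#' theoretical support `[d_min, d_max]` with mean 0 and variance 1.  The
#' two-sided `level` confidence limits of that density are the "neutral
#' mutation range": windows whose D falls outside it are candidate
#' selected regions.
#'
#' @param n sample size used for the limits (>= 4).  Whether accessions
#'   or haplotypes are fed here is the caller's convention; see
#'   [window_stats()] and the `ci_sample_size` pipeline option.
#' @param level two-sided confidence level in (0, 1); default 0.95 splits
#'   the tail mass equally (2.5% per side).
#' @return an object of class `neutral_range`: list with `n`, `level`,
#'   `d_min`, `d_max`, `alpha`, `beta`, `lower`, `upper`.
#' @examples
#' d_confidence_limits(8)  # lower ~ -1.663, upper ~ 1.975
#' @export
d_confidence_limits <- function(n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)")
  }
  b <- d_bounds(n)
  d_min <- b[["d_min"]]
  d_max <- b[["d_max"]]
  # Beta shape parameters of the mean-0 variance-1 density on
  # [d_min, d_max]; in the unit variable u = (D - d_min)/(d_max - d_min)
  # the density is Beta(shape1 = beta, shape2 = alpha).
  span <- d_max - d_min
  alpha <- -(1 + d_min * d_max) * d_max / span
  beta <- (1 + d_min * d_max) * d_min / span
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("beta approximation infeasible for n = ", n)
  }
  tail <- (1 - level) / 2
  lower <- d_min + stats::qbeta(tail, beta, alpha) * span
  upper <- d_min + stats::qbeta(1 - tail, beta, alpha) * span
  structure(list(n = n, level = level, d_min = d_min, d_max = d_max,
                 alpha = alpha, beta = beta, lower = lower, upper = upper),
            class = "neutral_range")
}

#' @export
print.neutral_range <- function(x, ...) {
  cat(sprintf(
    "neutral_range (n = %d, level = %.2f): D in [%.3f, %.3f], support [%.3f, %.3f]\n",
    x$n, x$level, x$lower, x$upper, x$d_min, x$d_max))
  invisible(x)
}

# CDF of the rescaled beta density of D; used by tests to check that the
# limits really are the level-quantiles.
neutral_range_cdf <- function(range, d) {
  stopifnot(inherits(range, "neutral_range"))
  u <- (d - range$d_min) / (range$d_max - range$d_min)
  stats::pbeta(u, range$beta, range$alpha)
}

#' Selective judgment of a window's D against a neutral range
#'
#' `TRUE` exactly when D lies strictly outside the open interval
#' `(lower, upper)` — i.e. in `(-Inf, lower) U (upper, Inf)`.  Undefined
#' (`NA`) D values are never judged and return `FALSE`.
#'
#' @param range a [d_confidence_limits()] result.
#' @param d Tajima's D value(s); `NA` allowed.
#' @return logical vector.
#' @export
selective_judgment <- function(range, d) {
  stopifnot(inherits(range, "neutral_range"))
  out <- !is.na(d) & (d < range$lower | d > range$upper)
  out
}

#' Tabulate neutral ranges for a span of sample sizes
#'
#' @param n_values integer vector of sample sizes.
#' @inheritParams d_confidence_limits
#' @return data.frame with one row per n: `n`, `d_min`, `d_max`,
#'   `lower`, `upper`.
#' @export
neutral_range_table <- function(n_values, level = 0.95) {
  rows <- lapply(n_values, function(n) {
    r <- d_confidence_limits(n, level)
    data.frame(n = n, level = level, d_min = r$d_min, d_max = r$d_max,
               lower = r$lower, upper = r$upper)
  })
  do.call(rbind, rows)
}
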