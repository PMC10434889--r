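# Discrete power-law fitting: MLE exponent with optional KS-minimizing xmin.
# The normalizing constant is the Hurwitz zeta function, evaluated by direct
# summation plus an Euler-Maclaurin tail.

hurwitz_zeta <- function(a, q, K = 1000L) {
  if (a <= 1) stop("zeta diverges for exponent <= 1")
  k <- 0:(K - 1L)
  head <- sum((q + k)^(-a))
  qk <- q + K
  tail <- qk^(1 - a) / (a - 1) + 0.5 * qk^(-a) + a * qk^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * qk^(-a - 3) / 720
  head + tail
}

#' Fit a discrete power law
#'
#' Maximum-likelihood fit of `P(x) ~ x^-exponent` for integer `x >= xmin`.
#' With `xmin = "auto"` the cutoff is chosen to minimize the
#' Kolmogorov-Smirnov distance between the empirical and fitted tail
#' distributions (candidate cutoffs are the observed values, thinned to at
#' most `max_xmin_candidates`). At least 50 tail observations are required.
#'
#' @param values Integer-valued observations (avalanche sizes, durations in
#'   bins, ...).
#' @param xmin Integer cutoff, or `"auto"` (default).
#' @param max_xmin_candidates Cap on scanned cutoffs (default 50).
#' @return Object of class `power_law_fit`: list with `exponent`, `xmin`,
#'   `n_tail`, `ks_distance`, `method`.
#' @export
fit_discrete_power_law <- function(values, xmin = "auto",
                                   max_xmin_candidates = 50L) {
  v <- as.numeric(values)
  v <- v[is.finite(v) & v >= 1]
  if (length(unique(v)) < 2L) stop("degenerate input: all values equal")
  if (identical(xmin, "auto")) {
    cand <- sort(unique(v))
    tail_n <- vapply(cand, function(m) sum(v >= m), 0)
    cand <- cand[tail_n >= 50L]
    if (!length(cand)) stop("need at least 50 tail observations")
    if (length(cand) > max_xmin_candidates)
      cand <- unique(round(stats::quantile(cand, probs = seq(0, 1, length.out = max_xmin_candidates), names = FALSE, type = 1)))
    fits <- lapply(cand, function(m) pl_mle(v, m))
    ks <- vapply(fits, `[[`, 0, "ks_distance")
    fits[[which.min(ks)]]
  } else {
    if (sum(v >= xmin) < 50L) stop("need at least 50 tail observations")
    pl_mle(v, xmin)
  }
}

pl_mle <- function(v, xmin) {
  tail_v <- v[v >= xmin]
  n <- length(tail_v)
  slx <- sum(log(tail_v))
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slx
  opt <- stats::optimize(nll, interval = c(1.001, 8))
  a <- opt$minimum
  structure(list(exponent = a, xmin = xmin, n_tail = n,
                 ks_distance = pl_ks(tail_v, a, xmin),
                 method = "discrete-mle"),
            class = "power_law_fit")
}

# KS distance between empirical tail CDF and the fitted discrete CDF
pl_ks <- function(tail_v, a, xmin) {
  z <- hurwitz_zeta(a, xmin)
  xs <- sort(unique(tail_v))
  emp <- stats::ecdf(tail_v)(xs)
  theo <- 1 - vapply(xs, function(x) hurwitz_zeta(a, x + 1), 0) / z
  max(abs(emp - theo))
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: exponent %.3f, xmin %g, n_tail %d, KS %.4f\n",
              x$exponent, x$xmin, x$n_tail, x$ks_distance))
  invisible(x)
}

#' Bootstrap confidence interval for a power-law exponent
#'
#' Nonparametric bootstrap: the tail observations are resampled with
#' replacement and the exponent refitted (at the original `xmin`), giving a
#' percentile interval.
#'
#' @param values Observations, as in [fit_discrete_power_law()].
#' @param fit A `power_law_fit` for `values`.
#' @param n_boot Number of resamples (default 500).
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `(lo, hi)`.
#' @export
power_law_exponent_ci <- function(values, fit, n_boot = 500L, level = 0.95) {
  v <- as.numeric(values)
  tail_v <- v[v >= fit$xmin]
  boots <- vapply(seq_len(n_boot), function(b) {
    pl_mle(sample(tail_v, replace = TRUE), fit$xmin)$exponent
  }, 0)
  unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF draws from `P(x) ~ x^-exponent`, `x >= xmin`. The CDF
#' is tabulated up to a cutoff covering all but a tiny tail mass; draws
#' beyond the cutoff are resolved by bisection on the Hurwitz-zeta CCDF.
#'
#' @param exponent Power-law exponent, `> 1`.
#' @param xmin Smallest value (integer `>= 1`).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer-valued numeric vector of length `n`.
#' @export
sample_discrete_power_law <- function(exponent, xmin = 1L, n = 1L, seed = NULL) {
  if (exponent <= 1) stop("exponent must exceed 1 (non-normalizable otherwise)")
  if (!is.null(seed)) set.seed(seed)
  Z <- hurwitz_zeta(exponent, xmin)
  cutoff <- 100000L
  xs <- xmin:(xmin + cutoff - 1L)
  cdf <- cumsum(xs^(-exponent)) / Z
  u <- stats::runif(n)
  out <- xs[findInterval(u, cdf) + 1L]  # first x with CDF(x) >= u
  over <- which(u > cdf[cutoff])
  if (length(over)) {
    ccdf <- function(x) hurwitz_zeta(exponent, x) / Z  # P(X >= x)
    for (i in over) {
      lo <- xs[cutoff]
      hi <- lo * 2
      while (ccdf(hi + 1) > 1 - u[i]) { lo <- hi; hi <- hi * 2 }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (ccdf(mid + 1) > 1 - u[i]) lo <- mid else hi <- mid
      }
      out[i] <- hi
    }
  }
  as.numeric(out)
}
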