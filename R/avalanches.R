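#' Detect neuronal avalanches
#'
#' The merged population spike train is binned (by default at its average
#' inter-spike interval); an avalanche is a maximal run of non-empty bins
#' delimited by empty bins on both sides. Size is the total spike count of
#' the run, duration its bin count times the bin width. Runs touching the
#' recording edges are discarded since they lack a delimiting empty bin.
#'
#' @param x A `spike_train_set`.
#' @param bin_width Bin width in seconds, or `"mean-isi"` (default) for the
#'   average inter-spike interval of the merged train.
#' @param window Optional `(start, end)` restriction (s).
#' @return Object of class `avalanche_catalog`: data frame with `start`
#'   (s), `duration` (s), `duration_bins`, `size`; attributes `bin_width`
#'   and `state`.
#' @export
detect_avalanches <- function(x, bin_width = "mean-isi", window = NULL) {
  t <- merged_spikes(x)
  if (is.null(window)) window <- c(x$t_start, x$t_end)
  t <- t[t >= window[1] & t < window[2]]
  if (identical(bin_width, "mean-isi")) {
    if (length(t) < 2L) stop("mean ISI undefined with fewer than 2 spikes")
    bin_width <- mean(diff(t))
  }
  n_bins <- floor((window[2] - window[1]) / bin_width + 1e-9)
  if (n_bins < 3L || length(t) == 0L)
    return(avalanche_catalog(numeric(0), integer(0), integer(0), bin_width))
  idx <- floor((t - window[1]) / bin_width + 1e-9) + 1L
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  r <- rle(counts > 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < n_bins  # interior runs only
  if (!any(keep))
    return(avalanche_catalog(numeric(0), integer(0), integer(0), bin_width))
  cs <- cumsum(counts)
  sizes <- cs[ends[keep]] - cs[starts[keep] - 1L]
  avalanche_catalog(window[1] + (starts[keep] - 1L) * bin_width,
                    r$lengths[keep], sizes, bin_width)
}

avalanche_catalog <- function(start, duration_bins, size, bin_width,
                              state = NA_character_) {
  structure(data.frame(start = start,
                       duration = as.numeric(duration_bins) * bin_width,
                       duration_bins = as.integer(duration_bins),
                       size = as.integer(size)),
            bin_width = bin_width, state = state,
            class = c("avalanche_catalog", "data.frame"))
}

#' @export
print.avalanche_catalog <- function(x, ...) {
  cat(sprintf("avalanche_catalog: %d avalanches, bin %.4g ms\n",
              nrow(x), 1000 * attr(x, "bin_width")))
  invisible(x)
}

#' Mean-size-versus-duration scaling exponent
#'
#' Computes the average avalanche size for each distinct duration and fits
#' an ordinary least-squares line to `log10(mean size)` against
#' `log10(duration)`. The slope estimates the scaling exponent `1/(sigma
#' nu z)` relating sizes to durations; at criticality it should match the
#' crackling-noise ratio `(tau_t - 1)/(tau - 1)`.
#'
#' @param cat An `avalanche_catalog`.
#' @return Object of class `scaling_fit`: list with `exponent`,
#'   `intercept`, `n_durations`, and the per-duration table.
#' @export
size_duration_scaling <- function(cat) {
  dur <- cat$duration_bins
  if (length(unique(dur)) < 3L) stop("need at least 3 distinct durations")
  mean_size <- tapply(cat$size, dur, mean)
  d <- as.numeric(names(mean_size)) * attr(cat, "bin_width")
  fit <- stats::lm.fit(cbind(1, log10(d)), log10(as.numeric(mean_size)))
  structure(list(exponent = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_durations = length(d),
                 table = data.frame(duration = d,
                                    mean_size = as.numeric(mean_size))),
            class = "scaling_fit")
}

#' Crackling-noise exponent ratio
#'
#' `(tau_t - 1)/(tau - 1)` from the duration and size power-law exponents;
#' equality with the size-duration scaling exponent is a stringent
#' criticality signature.
#'
#' @param size_fit,dur_fit `power_law_fit` objects (or bare exponents) for
#'   avalanche sizes and durations.
#' @return Numeric ratio.
#' @export
crackling_ratio <- function(size_fit, dur_fit) {
  tau <- if (inherits(size_fit, "power_law_fit")) size_fit$exponent else size_fit
  tau_t <- if (inherits(dur_fit, "power_law_fit")) dur_fit$exponent else dur_fit
  if (tau <= 1 || tau_t <= 1) stop("exponents must exceed 1")
  (tau_t - 1) / (tau - 1)
}
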