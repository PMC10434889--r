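#' Field signal container
#'
#' @param samples Numeric vector of samples (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param kind `"sLFP"` or `"LFP"`.
#' @return Object of class `field_signal`.
#' @export
field_signal <- function(samples, fs, kind = c("sLFP", "LFP")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("non-finite samples")
  if (fs <= 0) stop("fs must be positive")
  structure(list(samples = samples, fs = fs, kind = kind),
            class = "field_signal")
}

#' @export
print.field_signal <- function(x, ...) {
  cat(sprintf("field_signal (%s): %d samples at %g Hz (%.1f s)\n",
              x$kind, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Synthetic local field potential from excitatory spiking
#'
#' Each excitatory neuron's binned spike counts are convolved with a causal
#' exponentially decaying kernel `exp(-t/tau)` (unit peak, truncated at
#' `10 * tau`), modelling the postsynaptic potential each spike evokes; the
#' sLFP is the average of the convolved traces across neurons, so it is
#' linear in the spike input.
#'
#' @param x A `spike_train_set` with at least one excitatory neuron.
#' @param bin_width Spike-count bin (s). Default 0.008, i.e. a 125 Hz
#'   sampling rate (see Details).
#' @param tau Kernel time constant (s); default 0.024, a typical miniature
#'   EPSP timescale for frontal pyramidal neurons.
#' @param excitatory_only Use only excitatory-flagged neurons (default).
#' @param window Optional `(start, end)` window (s).
#' @return A `field_signal` of kind `"sLFP"` with `fs = 1/bin_width`.
#' @details The default 8 ms bin gives `fs = 125` Hz, which supports 1 Hz
#'   resolution Welch spectra from 1 s segments and matches typical
#'   down-sampled LFP rates; an 80 ms bin (12.5 Hz) can be requested
#'   through `bin_width` when coarser count windows are wanted.
#' @export
build_slfp <- function(x, bin_width = 0.008, tau = 0.024,
                       excitatory_only = TRUE, window = NULL) {
  stopifnot(inherits(x, "spike_train_set"))
  keep <- if (excitatory_only) x$excitatory else rep(TRUE, n_neurons(x))
  if (!any(keep)) stop("no excitatory neurons")
  sub <- x
  sub$spikes <- x$spikes[keep]
  sub$neuron_ids <- x$neuron_ids[keep]
  sub$excitatory <- x$excitatory[keep]
  traj <- bin_population(sub, bin_width, window)
  slfp_from_trajectory(traj, tau)
}

#' @rdname build_slfp
#' @param traj A `population_trajectory` of spike counts (e.g. with DOWN
#'   bins already excluded via [exclude_down_bins()]); all its neurons are
#'   used.
#' @export
slfp_from_trajectory <- function(traj, tau = 0.024) {
  stopifnot(inherits(traj, "population_trajectory"))
  bin_width <- traj$bin_width
  k <- exp(-(0:ceiling(10 * tau / bin_width)) * bin_width / tau)
  n_bins <- nrow(traj$counts)
  conv <- apply(traj$counts, 2L, function(s) causal_conv(s, k))
  if (n_bins == 1L) conv <- matrix(conv, nrow = 1L)
  field_signal(rowMeans(conv), fs = 1 / bin_width, kind = "sLFP")
}

# causal FIR convolution, output aligned with input, via FFT
causal_conv <- function(x, k) {
  n <- length(x)
  m <- n + length(k) - 1L
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                     stats::fft(c(k, numeric(m - length(k)))), inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over non-overlapping Hann-windowed
#' segments (default 1 s, giving 1 Hz frequency resolution). Each segment
#' is mean-detrended. One-sided density normalisation, so
#' `sum(psd) * df` approximates the signal variance.
#'
#' @param sig A `field_signal` (or numeric vector with `fs` attribute via
#'   `field_signal()`).
#' @param seg_len Segment length in seconds (default 1).
#' @return Object of class `spectral_result`: data frame with `freq` (Hz)
#'   and `psd`, attributes `fs`, `seg_len`, `n_segments`.
#' @export
welch_psd <- function(sig, seg_len = 1.0) {
  stopifnot(inherits(sig, "field_signal"))
  w <- welch_segments(sig, seg_len)
  psd <- Re(rowMeans(w$spec * Conj(w$spec)))
  out <- data.frame(freq = w$freq, psd = psd * w$scale)
  structure(out, fs = sig$fs, seg_len = seg_len, n_segments = w$n_seg,
            class = c("spectral_result", "data.frame"))
}

# shared segmentation: returns one-sided windowed FFTs per segment
welch_segments <- function(sig, seg_len) {
  x <- sig$samples
  L <- round(seg_len * sig$fs)
  n_seg <- length(x) %/% L
  if (n_seg < 2L) stop("signal shorter than two Welch segments")
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))  # periodic Hann
  half <- seq_len(L %/% 2 + 1L)
  spec <- vapply(seq_len(n_seg), function(s) {
    seg <- x[((s - 1L) * L + 1L):(s * L)]
    stats::fft((seg - mean(seg)) * w)[half]
  }, complex(length(half)))
  if (length(half) == 1L) spec <- matrix(spec, nrow = 1L)
  # one-sided density scaling; interior bins doubled
  scale <- rep(2, length(half)) / (sig$fs * sum(w^2))
  scale[1] <- scale[1] / 2
  if (L %% 2 == 0) scale[length(half)] <- scale[length(half)] / 2
  list(spec = spec, freq = (half - 1L) * sig$fs / L, scale = scale,
       n_seg = n_seg)
}

#' Magnitude-squared coherence between two field signals
#'
#' Welch cross-spectral estimate with the same segmentation as
#' [welch_psd()]: `C(f) = |<Sab>|^2 / (<Saa> <Sbb>)`, averaged over
#' segments before taking the ratio, so values lie in `[0, 1]`.
#'
#' @param a,b `field_signal`s with equal sampling rate and length.
#' @param seg_len Segment length in seconds.
#' @return A `spectral_result` data frame with `freq`, `coherence`.
#' @export
msc_coherence <- function(a, b, seg_len = 1.0) {
  stopifnot(inherits(a, "field_signal"), inherits(b, "field_signal"))
  if (a$fs != b$fs) stop("sampling rates differ")
  if (length(a$samples) != length(b$samples)) stop("signal lengths differ")
  wa <- welch_segments(a, seg_len)
  wb <- welch_segments(b, seg_len)
  saa <- Re(rowMeans(wa$spec * Conj(wa$spec)))
  sbb <- Re(rowMeans(wb$spec * Conj(wb$spec)))
  sab <- rowMeans(wa$spec * Conj(wb$spec))
  coh <- Mod(sab)^2 / pmax(saa * sbb, .Machine$double.xmin)
  structure(data.frame(freq = wa$freq, coherence = pmin(coh, 1)),
            fs = a$fs, seg_len = seg_len, n_segments = wa$n_seg,
            class = c("spectral_result", "data.frame"))
}

#' Spectral power-law decay exponent
#'
#' Ordinary least-squares fit of `log10(psd)` on `log10(f)` over a
#' frequency range; the exponent alpha of an `f^-alpha` decay is the
#' negative slope.
#'
#' @param spec A `spectral_result` with a `psd` column.
#' @param f_range Length-2 numeric `(f_lo, f_hi)` in Hz.
#' @return Numeric alpha.
#' @export
spectral_slope <- function(spec, f_range) {
  sel <- spec$freq >= f_range[1] & spec$freq <= f_range[2] & spec$freq > 0
  if (sum(sel) < 5L) stop("need at least 5 positive frequencies in range")
  if (any(spec$psd[sel] <= 0)) stop("non-positive psd values in range")
  fit <- stats::lm.fit(cbind(1, log10(spec$freq[sel])), log10(spec$psd[sel]))
  -unname(fit$coefficients[2])
}

#' Band power fraction
#'
#' Fraction of total spectral power within a frequency band; used to test
#' for the delta-band (0-4 Hz) peak of slow-wave activity.
#'
#' @param spec A `spectral_result` with a `psd` column.
#' @param band Length-2 numeric `(f_lo, f_hi)` in Hz.
#' @return Numeric in `[0, 1]`.
#' @export
band_power_fraction <- function(spec, band = c(0, 4)) {
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  sum(spec$psd[sel]) / sum(spec$psd)
}

#' Downsample and average field traces
#'
#' Utility to match real field recordings to the sLFP grid: averages
#' channels and decimates by an integer factor (plain subsampling after a
#' block-mean anti-alias step).
#'
#' @param mat Numeric matrix, samples x channels (or vector).
#' @param fs Input sampling rate (Hz).
#' @param factor Integer decimation factor.
#' @return A `field_signal` of kind `"LFP"` at `fs / factor`.
#' @export
resample_average <- function(mat, fs, factor = 1L) {
  x <- if (is.matrix(mat)) rowMeans(mat) else as.numeric(mat)
  factor <- as.integer(factor)
  if (factor > 1L) {
    n <- (length(x) %/% factor) * factor
    x <- colMeans(matrix(x[seq_len(n)], nrow = factor))
  }
  field_signal(x, fs / factor, kind = "LFP")
}
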