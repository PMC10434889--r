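test_that("sLFP is the kernel-convolved population average", {
  # no spikes: all-zero signal
  empty <- spike_train_set(list(a = numeric(0)), t_start = 0, t_end = 1)
  expect_true(all(build_slfp(empty)$samples == 0))

  # single spike in bin 0: samples follow exp(-t/tau) with unit peak
  one <- spike_train_set(list(a = 0.001), t_start = 0, t_end = 0.2)
  sl <- build_slfp(one, bin_width = 0.008, tau = 0.024)
  expect_equal(sl$fs, 125)
  expect_equal(sl$samples[1:3] / max(sl$samples),
               c(1, exp(-8 / 24), exp(-16 / 24)), tolerance = 1e-9)

  # linearity: the merged population is the neuron-count-weighted average
  set.seed(4)
  a <- spike_train_set(list(x = sort(runif(40, 0, 2))), t_start = 0, t_end = 2)
  b <- spike_train_set(list(y = sort(runif(25, 0, 2)),
                            z = sort(runif(30, 0, 2))), t_start = 0, t_end = 2)
  ab <- spike_train_set(c(a$spikes, b$spikes), t_start = 0, t_end = 2)
  merged <- build_slfp(ab)
  weighted <- (1 * build_slfp(a)$samples + 2 * build_slfp(b)$samples) / 3
  expect_equal(merged$samples, weighted, tolerance = 1e-12)

  inh <- spike_train_set(list(a = 0.5), excitatory = FALSE,
                         t_start = 0, t_end = 1)
  expect_error(build_slfp(inh), "no excitatory")
})

test_that("Welch PSD finds spectral lines and respects Parseval", {
  fs <- 125
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ps <- welch_psd(field_signal(sin(2 * pi * 4 * t), fs))
  expect_equal(ps$freq[which.max(ps$psd)], 4)
  expect_equal(diff(ps$freq)[1], 1)  # 1 Hz resolution from 1 s segments

  set.seed(8)
  wn <- field_signal(rnorm(fs * 120), fs)
  pw <- welch_psd(wn)
  expect_lt(abs(sum(pw$psd) * 1 / var(wn$samples) - 1), 0.05)

  expect_error(welch_psd(field_signal(rnorm(100), fs)), "two Welch segments")
})

test_that("magnitude-squared coherence behaves as an MSC estimator", {
  fs <- 125
  set.seed(9)
  a <- field_signal(rnorm(fs * 120), fs)
  expect_true(all(abs(msc_coherence(a, a)$coherence - 1) < 1e-9))

  b <- field_signal(rnorm(fs * 120), fs)
  expect_lte(mean(msc_coherence(a, b)$coherence), 0.2)  # >= 100 segments

  # analytic MSC = SNR/(1+SNR): coherence decreases with added noise power
  coh_at <- function(noise_sd) {
    noisy <- field_signal(a$samples + rnorm(length(a$samples), 0, noise_sd), fs)
    mean(msc_coherence(a, noisy)$coherence)
  }
  c1 <- coh_at(0.5); c2 <- coh_at(1); c3 <- coh_at(2)
  expect_gt(c1, c2); expect_gt(c2, c3)
  expect_equal(c2, 1 / (1 + 1), tolerance = 0.05)  # SNR = 1

  short <- field_signal(rnorm(fs), fs)
  expect_error(msc_coherence(a, field_signal(rnorm(100), 100)), "rates differ")
})

test_that("spectral slope recovers power-law decay exponents", {
  exact <- structure(data.frame(freq = 1:50, psd = (1:50)^-2),
                     class = c("spectral_result", "data.frame"))
  expect_equal(spectral_slope(exact, c(1, 50)), 2, tolerance = 1e-12)

  fs <- 125
  set.seed(10)
  wn <- welch_psd(field_signal(rnorm(fs * 300), fs))
  expect_lt(abs(spectral_slope(wn, c(2, 50))), 0.1)

  brown <- welch_psd(field_signal(cumsum(rnorm(fs * 300)), fs))
  expect_equal(spectral_slope(brown, c(2, 40)), 2, tolerance = 0.15)

  expect_error(spectral_slope(exact, c(40, 42)), "at least 5")
  bad <- structure(data.frame(freq = 1:10, psd = c(rep(1, 9), 0)),
                   class = c("spectral_result", "data.frame"))
  expect_error(spectral_slope(bad, c(1, 10)), "non-positive")
})

test_that("SWS-like sLFP concentrates power in the delta band", {
  ses <- neo_session(seed = 42)
  sws <- welch_psd(build_slfp(ses$spikes, window = c(300, 600)))
  # rate-matched Poisson reference: the Wake epochs of the same session
  wake <- welch_psd(build_slfp(ses$spikes, window = c(0, 300)))
  expect_gt(band_power_fraction(sws, c(0, 4)),
            band_power_fraction(wake, c(0, 4)))
  # the delta peak: SWS has a local PSD maximum in 0.5-4 Hz above its own
  # 8-20 Hz floor, by a larger factor than Wake
  ratio <- function(ps) max(ps$psd[ps$freq >= 1 & ps$freq <= 4]) /
    mean(ps$psd[ps$freq >= 8 & ps$freq <= 20])
  expect_gt(ratio(sws), 2 * ratio(wake))
})

test_that("resample_average decimates and averages channels", {
  m <- cbind(rep(1, 100), rep(3, 100))
  out <- resample_average(m, fs = 1000, factor = 10)
  expect_equal(out$fs, 100)
  expect_equal(length(out$samples), 10L)
  expect_true(all(out$samples == 2))
})
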