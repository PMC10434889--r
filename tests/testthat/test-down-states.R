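test_that("OFF periods are population-silence gaps within duration bounds", {
  # merged spikes every 20 ms: no gap reaches 50 ms
  dense <- spike_train_set(list(a = seq(0, 2, by = 0.02)), t_start = 0, t_end = 2)
  expect_equal(nrow(detect_off_periods(dense)), 0L)

  # gaps of 40 ms (too short), 80 ms (OFF), 1380 ms (too long)
  sts <- spike_train_set(list(a = c(0, 0.04, 0.12, 1.50)), t_start = 0, t_end = 2)
  off <- detect_off_periods(sts)
  expect_equal(nrow(off), 1L)
  expect_equal(off$start, 0.04)
  expect_equal(off$end, 0.12)

  # boundary durations are inclusive on both ends
  b <- spike_train_set(list(a = c(0, 0.05, 1.30)), t_start = 0, t_end = 2)
  expect_equal(nrow(detect_off_periods(b)), 2L)

  expect_error(detect_off_periods(spike_train_set(list(a = numeric(0)))),
               "empty")
})

test_that("OFF intervals never overlap and never contain a population spike", {
  ses <- neo_session(seed = 9)
  off <- detect_off_periods(ses$spikes)
  expect_true(all(off$start[-1] >= off$end[-nrow(off)]))
  t <- merged_spikes(ses$spikes)
  for (i in seq_len(nrow(off)))
    expect_equal(sum(t > off$start[i] & t < off$end[i]), 0L)
})

test_that("ON periods satisfy both the spike-count and duration criteria", {
  # two OFF periods around a 300 ms segment carrying 12 spikes
  seg <- seq(1.10, 1.40, length.out = 12)
  sts <- spike_train_set(list(a = c(0.9, 1.0, seg, 1.5, 1.6)),
                         t_start = 0, t_end = 2)
  off <- interval_set(c(1.0, 1.40), c(1.10, 1.50), "OFF")
  on <- detect_on_periods(sts, off)
  expect_equal(nrow(on), 1L)
  expect_equal(on$start, 1.10)
  expect_equal(on$end, 1.40)

  # only 5 spikes: rejected
  seg5 <- seq(1.10, 1.40, length.out = 5)
  sts5 <- spike_train_set(list(a = c(0.9, 1.0, seg5, 1.5, 1.6)),
                          t_start = 0, t_end = 2)
  expect_equal(nrow(detect_on_periods(sts5, off)), 0L)

  # 5 s segment with 500 spikes: too long
  segL <- seq(1.10, 6.10, length.out = 500)
  stsL <- spike_train_set(list(a = c(0.9, 1.0, segL, 6.2, 6.3)),
                          t_start = 0, t_end = 7)
  offL <- interval_set(c(1.0, 6.10), c(1.10, 6.20), "OFF")
  expect_equal(nrow(detect_on_periods(stsL, offL)), 0L)
})

test_that("fraction rule marks bins with strictly under 10% active neurons", {
  full <- population_trajectory(matrix(1L, 5, 20), 0.05)
  expect_equal(as.integer(detect_fraction_down(full)), rep(0L, 5))

  counts <- matrix(0L, 3, 20)
  counts[1, 1] <- 1L       # 5% active -> DOWN
  counts[2, 1:2] <- 1L     # exactly 10% -> not DOWN (strict <)
  counts[3, 1:5] <- 1L     # 25% -> not DOWN
  d <- detect_fraction_down(population_trajectory(counts, 0.05))
  expect_equal(as.integer(d), c(1L, 0L, 0L))

  expect_error(detect_fraction_down(full, fraction = 1.5), "fraction")
  expect_warning(detect_fraction_down(
    population_trajectory(matrix(0L, 2, 5), 0.05)), "fewer than 10")
})

test_that("interval rasterization round-trips within one bin", {
  traj <- population_trajectory(matrix(0L, 100, 3), 0.05,
                                bin_starts = seq(0, 4.95, by = 0.05))
  off <- interval_set(c(0.50, 2.12), c(0.85, 3.0), "OFF")
  down <- intervals_to_down_series(off, traj)
  expect_equal(sum(down), 7 + 18)  # majority-covered bins only
  back <- down_series_to_intervals(down)
  expect_equal(nrow(back), 2L)
  expect_lt(max(abs(back$start - off$start)), 0.05 + 1e-9)
  expect_lt(max(abs(back$end - off$end)), 0.05 + 1e-9)
})

test_that("point-biserial correlation matches its closed form", {
  down <- structure(c(1L, 1L, 0L, 0L, 1L, 0L), class = "down_state_series")
  prof <- c(10, 10, 0, 0, 10, 0)
  expect_equal(correlate_down_recurrence(down, prof)$r, 1.0)

  # frozen against an independent implementation of pointbiserialr
  d2 <- structure(c(1L, 1L, 0L, 0L), class = "down_state_series")
  r2 <- correlate_down_recurrence(d2, c(5, 3, 1, 1))
  expect_equal(r2$r, 0.9045340337332908, tolerance = 1e-12)
  expect_equal(r2$p_value, 0.09546596626670922, tolerance = 1e-9)
  # and against the equivalent Pearson correlation test
  ct <- stats::cor.test(c(1, 1, 0, 0), c(5, 3, 1, 1))
  expect_equal(r2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r2$p_value, ct$p.value, tolerance = 1e-12)

  expect_error(correlate_down_recurrence(
    structure(c(1L, 1L), class = "down_state_series"), c(1, 2)), "single class")
  expect_error(correlate_down_recurrence(d2, rep(4, 4)), "constant")
})

test_that("DOWN states drive the recurrence profile on synthetic SWS", {
  ses <- neo_session(seed = 15)
  sws <- state_trajectory(ses$spikes, ses$hypnogram, "SWS")
  eps <- wake_epsilon(ses$spikes, ses$hypnogram)
  sub <- population_trajectory(sws$counts[1:200, ], 0.05,
                               bin_starts = sws$bin_starts[1:200])
  prof <- recurrence_time_profile(recurrence_matrix(sub, eps))
  down <- intervals_to_down_series(ses$down, sub)
  res <- correlate_down_recurrence(down, prof)
  expect_gt(res$r, 0.5)
  expect_lt(res$p_value, 1e-10)
})

test_that("excluding DOWN bins compresses the trajectory", {
  traj <- population_trajectory(matrix(rpois(200 * 4, 1), 200, 4), 0.05)
  none <- structure(rep(0L, 200), class = "down_state_series")
  expect_equal(exclude_down_bins(traj, none)$counts, traj$counts)

  fifty <- structure(rep(c(1L, 0L, 0L, 0L), 50), class = "down_state_series")
  out <- exclude_down_bins(traj, fifty)
  expect_equal(nrow(out$counts), 150L)
  expect_true(attr(out, "time_compressed"))

  all_down <- structure(rep(1L, 200), class = "down_state_series")
  expect_error(exclude_down_bins(traj, all_down), "all bins")
})

test_that("planted DOWN intervals are recovered with high overlap and precision", {
  ses <- neo_session(seed = 31)
  off <- detect_off_periods(ses$spikes)
  off_sws <- off[off$start >= 300 & off$end <= 600, , drop = FALSE]
  expect_gte(interval_jaccard(off_sws, ses$down), 0.9)

  # per-interval recall and precision at 1 ms resolution
  grid <- seq(300.0005, 599.9995, by = 0.001)
  in_true <- sleepdyn:::in_intervals(grid, ses$down$start, ses$down$end)
  in_det <- sleepdyn:::in_intervals(grid, off_sws$start, off_sws$end)
  recall <- sum(in_true & in_det) / sum(in_true)
  precision <- sum(in_true & in_det) / sum(in_det)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
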