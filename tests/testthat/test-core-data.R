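test_that("spike table I/O reads back what was written", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("neuron_id\ttime_s", "n1\t0.10", "n1\t0.25", "n2\t0.12"), path)
  sts <- load_spikes(path)
  expect_equal(n_neurons(sts), 2L)
  expect_equal(n_spikes(sts), 3L)
  expect_gte(sts$t_end, 0.25)
  expect_equal(sts$spikes$n1, c(0.10, 0.25))

  # empty table with header only
  writeLines("neuron_id\ttime_s", path)
  expect_equal(n_neurons(load_spikes(path)), 0L)

  # malformed row reported with its line number
  writeLines(c("neuron_id\ttime_s", "n1\t0.10", "n1\tnot_a_time"), path)
  expect_error(load_spikes(path), "line 3")
})

test_that("write -> load round trip is lossless at 1e-9 s with metadata", {
  ses <- neo_session(seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spikes(ses$spikes, path)
  back <- load_spikes(path)
  expect_equal(back$neuron_ids, ses$spikes$neuron_ids)
  for (id in back$neuron_ids)
    expect_equal(back$spikes[[id]], ses$spikes$spikes[[id]], tolerance = 1e-9)
  expect_identical(back$region, "synthetic")
  expect_identical(unname(back$excitatory), unname(ses$spikes$excitatory))

  hpath <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(ses$hypnogram, hpath)
  expect_equal(load_hypnogram(hpath)$state, ses$hypnogram$state)
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_intervals(ses$down, ipath)
  back_i <- load_intervals(ipath)
  expect_equal(back_i$start, ses$down$start, tolerance = 1e-9)
  expect_identical(attr(back_i, "label"), "DOWN")
})

test_that("constructors enforce their invariants", {
  expect_error(spike_train_set(list(a = 1, a = 2)), "unique")
  expect_error(spike_train_set(list(a = c(0.5, NA))), "non-finite")
  expect_error(spike_train_set(list(a = 5), t_end = 1), "outside")
  expect_error(hypnogram(c(0, 1), c(2, 3), c("Wake", "SWS")), "overlap")
  expect_error(hypnogram(0, 1, "Nap"), "unknown state")
  expect_error(interval_set(1, 1), "end > start")
})

test_that("state restriction keeps half-open epochs and warns on absent states", {
  sts <- spike_train_set(list(a = c(1.0, 2.0, 5.0)), t_start = 0, t_end = 10)
  hyp <- hypnogram(c(0, 2), c(2, 10), c("Wake", "SWS"))
  wake <- restrict_to_state(sts, hyp, "Wake")
  expect_equal(wake$spikes$a, 1.0)  # spike at 2.0 belongs to SWS, not Wake
  sws <- restrict_to_state(sts, hyp, "SWS")
  expect_equal(sws$spikes$a, c(2.0, 5.0))
  expect_warning(rem <- restrict_to_state(sts, hyp, "REM"), "no epochs")
  expect_equal(n_spikes(rem), 0L)
})

test_that("per-state spike counts of a labelled synthetic session are recovered", {
  ses <- neo_session(seed = 11)
  by_state <- vapply(c("Wake", "SWS", "REM"), function(st)
    n_spikes(restrict_to_state(ses$spikes, ses$hypnogram, st)), 0L)
  expect_equal(sum(by_state), n_spikes(ses$spikes))
  # SWS has silent DOWN periods, so it must carry fewer spikes than Wake
  expect_lt(by_state[["SWS"]], by_state[["Wake"]])
})

test_that("binning counts spikes into half-open bins and drops the partial tail", {
  sts <- spike_train_set(list(a = c(0.01, 0.04, 0.06)), t_start = 0, t_end = 0.1)
  traj <- bin_population(sts, 0.05, window = c(0, 0.10))
  expect_equal(as.vector(traj$counts), c(2L, 1L))

  # 10 s window at 50 ms gives T = 200
  sts2 <- spike_train_set(list(a = c(0.2, 5)), t_start = 0, t_end = 10)
  expect_equal(nrow(bin_population(sts2, 0.05)$counts), 200L)

  expect_error(bin_population(sts, 0.05, window = c(0, 0.01)), "shorter")
})

test_that("spike count is conserved for any bin width covering the window", {
  ses <- short_session(seed = 3)
  for (bw in c(0.02, 0.05, 0.13)) {
    window <- c(0, floor(360 / bw) * bw)
    traj <- bin_population(ses$spikes, bw, window = window)
    in_window <- sum(merged_spikes(ses$spikes) < window[2])
    expect_equal(sum(traj$counts), in_window)
  }
})

test_that("restricting then binning equals binning then restricting on aligned epochs", {
  ses <- short_session(seed = 5)
  hyp <- ses$hypnogram  # epoch bounds are multiples of the bin width
  sws_first <- bin_population(restrict_to_state(ses$spikes, hyp, "SWS"), 0.05,
                              window = c(120, 240))
  all_bins <- bin_population(ses$spikes, 0.05, window = c(0, 360))
  idx <- all_bins$bin_starts >= 120 & all_bins$bin_starts < 240
  expect_equal(sws_first$counts, all_bins$counts[idx, , drop = FALSE],
               ignore_attr = TRUE)
})
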