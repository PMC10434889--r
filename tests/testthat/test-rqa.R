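test_that("wake epsilon is the population SD of summed Wake counts", {
  # constant summed counts: one neuron, one spike per 50 ms bin
  sts <- spike_train_set(list(a = seq(0.025, 9.975, by = 0.05)),
                         t_start = 0, t_end = 10)
  hyp <- hypnogram(0, 10, "Wake")
  expect_equal(wake_epsilon(sts, hyp), 0)

  # summed counts 2,4,6,8 -> population SD sqrt(5)
  times <- unlist(lapply(1:4, function(b)
    seq_len(2 * b) * 1e-3 + (b - 1) * 0.05))
  sts2 <- spike_train_set(list(a = sort(times)), t_start = 0, t_end = 0.2)
  expect_equal(wake_epsilon(sts2, hypnogram(0, 0.2, "Wake")),
               sqrt(5), tolerance = 1e-12)

  expect_error(wake_epsilon(sts2, hypnogram(0, 0.2, "SWS")), "epsilon undefined")
})

test_that("recurrence matrix follows the inclusive epsilon rule", {
  const <- population_trajectory(matrix(3L, 10, 2), 0.05)
  expect_true(all(recurrence_matrix(const, 0)$R))

  # epsilon = 0 marks exactly the repeats of the same firing pattern
  cc <- matrix(c(1, 2, 1, 3), ncol = 1)
  rp0 <- recurrence_matrix(population_trajectory(cc, 0.05), 0)
  expect_equal(unname(rp0$R + 0),
               rbind(c(1, 0, 1, 0), c(0, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 0, 1)))

  # one neuron, counts 0,3,0,3 at epsilon 1: checkerboard
  rp <- recurrence_matrix(population_trajectory(matrix(c(0, 3, 0, 3)), 0.05), 1)
  expect_equal(unname(rp$R + 0),
               rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_true(isSymmetric(rp$R))
  expect_true(all(diag(rp$R)))
})

test_that("RQA metrics match hand-derived values on canonical plots", {
  checker <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  m <- rqa_metrics(checker)
  expect_equal(m$RR, 0.5)
  expect_equal(m$DET, 1.0)
  expect_equal(m$LAM, 0)
  expect_equal(m$TT, 0)
  expect_equal(m$DIV, 0.5)

  ones <- matrix(1, 200, 200)
  m1 <- rqa_metrics(ones)
  expect_equal(m1$RR, 1)
  # two corner diagonals of length 1 keep DET just below 1 (LOI excluded)
  expect_equal(m1$DET, 39798 / 39800)
  expect_gt(m1$DET, 0.9999)
  expect_equal(m1$LAM, 1)
  expect_equal(m1$TT, 200)
  expect_equal(m1$DIV, 1 / 199)

  ident <- diag(1, 5)
  mi <- rqa_metrics(ident)
  expect_equal(mi$RR, 0.2)
  expect_equal(mi$DET, 0)
  expect_equal(mi$LAM, 0)
  expect_equal(mi$TT, 0)
  expect_equal(mi$DIV, 1)  # isolated points only

  expect_error(rqa_metrics(matrix(1, 2, 3)), "square")
  expect_error(rqa_metrics(checker, l_min = 1), ">= 2")
})

test_that("fast line histograms agree exactly with the brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    R <- random_recurrence(30, p = stats::runif(1, 0.05, 0.6))
    fast <- rqa_metrics(R)
    slow <- rqa_oracle(R)
    expect_identical(fast$RR, slow$RR)
    expect_identical(fast$DET, slow$DET)
    expect_identical(fast$LAM, slow$LAM)
    expect_identical(fast$TT, slow$TT)
    expect_identical(fast$DIV, slow$DIV)
  }
})

test_that("RR is non-decreasing in epsilon and invariant to neuron order", {
  set.seed(1)
  counts <- matrix(rpois(100 * 8, 1.5), 100, 8)
  traj <- population_trajectory(counts, 0.05)
  rr <- vapply(c(0, 0.5, 1, 2, 4, 8), function(e)
    rqa_metrics(recurrence_matrix(traj, e))$RR, 0)
  expect_true(all(diff(rr) >= 0))

  perm <- population_trajectory(counts[, sample(8)], 0.05)
  for (e in c(1, 3)) {
    m1 <- rqa_metrics(recurrence_matrix(traj, e))
    m2 <- rqa_metrics(recurrence_matrix(perm, e))
    expect_equal(m1[c("RR", "DET", "LAM", "TT", "DIV")],
                 m2[c("RR", "DET", "LAM", "TT", "DIV")])
  }
})

test_that("windowed RQA splits into standalone windows", {
  set.seed(2)
  traj <- population_trajectory(matrix(rpois(600 * 5, 1), 600, 5), 0.05)
  wm <- windowed_rqa(traj, 2, window_len = 10)
  expect_equal(nrow(wm), 3L)  # 30 s at 10 s windows
  sub <- population_trajectory(traj$counts[201:400, ], 0.05)
  m2 <- rqa_metrics(recurrence_matrix(sub, 2))
  expect_equal(wm$RR[2], m2$RR)
  expect_equal(wm$DET[2], m2$DET)
  expect_equal(wm$TT[2], m2$TT)

  short <- population_trajectory(traj$counts[1:100, ], 0.05)
  expect_warning(empty <- windowed_rqa(short, 2, window_len = 10), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("SWS-like windows recur more than Wake-like windows", {
  ses <- short_session(seed = 21)
  eps <- wake_epsilon(ses$spikes, ses$hypnogram)
  rr_wake <- mean(windowed_rqa(
    state_trajectory(ses$spikes, ses$hypnogram, "Wake"), eps)$RR)
  rr_sws <- mean(windowed_rqa(
    state_trajectory(ses$spikes, ses$hypnogram, "SWS"), eps)$RR)
  expect_gt(rr_sws, rr_wake)
})

test_that("recurrence profile is the column sums", {
  ones <- matrix(1, 4, 4)
  expect_equal(recurrence_time_profile(ones), rep(4, 4))
  expect_equal(recurrence_time_profile(diag(1, 4)), rep(1, 4))
  checker <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(recurrence_time_profile(checker), rep(2, 4))
})
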