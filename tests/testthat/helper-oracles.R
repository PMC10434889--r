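# Independent brute-force oracles and small fixture builders.

# Brute-force RQA oracle: explicit scans of every diagonal and column,
# no shared code with the package implementation.
rqa_oracle <- function(R, l_min = 2L, v_min = 2L) {
  R <- R > 0
  n <- nrow(R)
  diag_runs <- integer(0)
  for (off in c(-(n - 1):-1, 1:(n - 1))) {
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1L && j <= n && R[i, j]) {
        run <- run + 1L
      } else {
        if (run > 0L) diag_runs <- c(diag_runs, run)
        run <- 0L
      }
    }
    if (run > 0L) diag_runs <- c(diag_runs, run)
  }
  vert_runs <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (R[i, j]) {
        run <- run + 1L
      } else {
        if (run > 0L) vert_runs <- c(vert_runs, run)
        run <- 0L
      }
    }
    if (run > 0L) vert_runs <- c(vert_runs, run)
  }
  n_pts <- sum(R)
  d_tot <- sum(diag_runs)
  v_sel <- vert_runs[vert_runs >= v_min]
  list(
    RR = n_pts / n^2,
    DET = if (d_tot > 0) sum(diag_runs[diag_runs >= l_min]) / d_tot else 0,
    LAM = if (n_pts > 0) sum(v_sel) / n_pts else 0,
    TT = if (length(v_sel)) mean(v_sel) else 0,
    DIV = 1 / max(c(diag_runs, 1L)))
}

# random symmetric binary matrix with reflexive diagonal
random_recurrence <- function(n, p = 0.3) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  m <- m | t(m)
  diag(m) <- TRUE
  m
}

# Brute-force sample-entropy oracle: direct double loop over template pairs.
sampen_oracle <- function(z, m, r) {
  count <- function(len) {
    nv <- length(z) - m  # same template count at both lengths
    tot <- 0L
    for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
      d <- max(abs(z[i:(i + len - 1L)] - z[j:(j + len - 1L)]))
      if (d < r || d == 0) tot <- tot + 1L
    }
    tot
  }
  B <- count(m); A <- count(m + 1L)
  -log(A / B)
}

# tiny two-neuron fixture with hand-placed spikes
toy_spikes <- function() {
  spike_train_set(list(n1 = c(0.10, 0.25), n2 = c(0.12)), t_start = 0,
                  t_end = 0.3)
}

# session generators used across tests (fixed study conditions)
neo_session <- function(seed) gen_session(session_spec(seed = seed))
hip_session <- function(seed)
  gen_session(session_spec(down_firing_fraction = 0.1, seed = seed))

# shorter schedule for quicker pipeline tests
short_session <- function(seed, epoch = 120) {
  sch <- hypnogram(c(0, epoch, 2 * epoch), c(epoch, 2 * epoch, 3 * epoch),
                   c("Wake", "SWS", "REM"))
  gen_session(session_spec(schedule = sch, seed = seed))
}
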