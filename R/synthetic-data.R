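#' Synthetic session specification
#'
#' Parameters of the ground-truth-labelled session generator, which
#' emulates the statistical structure of multi-electrode sleep recordings:
#' ~50 simultaneously recorded neurons with lognormal firing rates
#' (median 2 Hz), asynchronous irregular (Poisson) firing during Wake and
#' REM, and slow-wave sleep as a semi-Markov alternation of UP periods
#' (uniform 200-4000 ms) and DOWN periods (uniform 50-1250 ms). During
#' DOWN periods either no neuron fires (neocortex-like) or a fixed 10%
#' subset keeps a low rate (hippocampus-like).
#'
#' @param n_neurons Number of neurons (default 50).
#' @param rate_meanlog,rate_sdlog Lognormal firing-rate parameters (Hz);
#'   defaults give median 2 Hz with realistic spread.
#' @param schedule A [hypnogram()]; default alternates
#'   Wake/SWS/REM epochs.
#' @param down_range,up_range Uniform duration bounds (s) of DOWN and UP
#'   periods.
#' @param down_firing_fraction Fraction of neurons active during DOWN
#'   periods: 0 (neocortex-like) or e.g. 0.1 (hippocampus-like).
#' @param down_rate Firing rate (Hz) of DOWN-active neurons.
#' @param frac_excitatory Fraction of neurons flagged excitatory.
#' @param seed Integer seed; identical spec gives identical output.
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(n_neurons = 50L, rate_meanlog = log(2),
                         rate_sdlog = 0.6, schedule = NULL,
                         down_range = c(0.050, 1.250),
                         up_range = c(0.200, 4.000),
                         down_firing_fraction = 0, down_rate = 2,
                         frac_excitatory = 0.8, seed = 1L) {
  if (is.null(schedule))
    schedule <- hypnogram(c(0, 300, 600), c(300, 600, 900),
                          c("Wake", "SWS", "REM"))
  stopifnot(down_firing_fraction >= 0, down_firing_fraction < 1,
            down_range[1] < down_range[2], up_range[1] < up_range[2])
  structure(list(n_neurons = as.integer(n_neurons),
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 schedule = schedule, down_range = down_range,
                 up_range = up_range,
                 down_firing_fraction = down_firing_fraction,
                 down_rate = down_rate, frac_excitatory = frac_excitatory,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Generate a ground-truth-labelled synthetic session
#'
#' Wake and REM epochs get independent Poisson spiking at the per-neuron
#' rates. SWS epochs alternate UP and DOWN periods with uniform durations;
#' UP periods fire at the same per-neuron rates as Wake (UP states as
#' fragments of wakefulness), so the UP-only activity is rate-matched to
#' Wake and the SWS mean rate is lower by the DOWN-time fraction. DOWN
#' periods are silent
#' (neocortex-like) or host a fixed low-rate subset of neurons
#' (hippocampus-like). The exact DOWN intervals are returned as ground
#' truth.
#'
#' @param spec A [session_spec()].
#' @return List with `spikes` (a `spike_train_set`), `hypnogram`, `down`
#'   (ground-truth DOWN `interval_set`), and `rates` (per-neuron Hz).
#' @export
gen_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(spec$seed)
  N <- spec$n_neurons
  rates <- stats::rlnorm(N, spec$rate_meanlog, spec$rate_sdlog)
  ids <- sprintf("n%02d", seq_len(N))
  sch <- spec$schedule
  if (!any(sch$state == "SWS") &&
      (spec$down_firing_fraction > 0 || !identical(spec$down_range, c(0.050, 1.250))))
    warning("schedule has no SWS epochs; DOWN parameters unused")
  down_active <- seq_len(max(0L, round(spec$down_firing_fraction * N)))
  spikes <- replicate(N, numeric(0), simplify = FALSE)
  down_s <- numeric(0); down_e <- numeric(0)
  # UP periods and Wake/REM epochs fire at the same per-neuron rates (UP
  # states as fragments of wakefulness), under the persistent-activity
  # constraint of fill_population_gaps()
  gen_segment <- function(s, e) {
    seg <- lapply(seq_len(N), function(k) poisson_train(rates[k], s, e))
    fill_population_gaps(seg, s, e)
  }
  append_seg <- function(seg) {
    for (k in seq_len(N))
      if (length(seg[[k]])) spikes[[k]] <<- c(spikes[[k]], seg[[k]])
  }
  for (i in seq_len(nrow(sch))) {
    a <- sch$start[i]; b <- sch$end[i]
    if (sch$state[i] != "SWS") {
      append_seg(gen_segment(a, b))
    } else {
      per <- sws_periods(a, b, spec)
      for (j in seq_len(nrow(per))) {
        s <- per$start[j]; e <- per$end[j]
        if (per$up[j]) {
          append_seg(gen_segment(s, e))
        } else {
          down_s <- c(down_s, s); down_e <- c(down_e, e)
          for (k in down_active)
            spikes[[k]] <- c(spikes[[k]], poisson_train(spec$down_rate, s, e))
        }
      }
    }
  }
  names(spikes) <- ids
  exc <- seq_len(N) <= round(spec$frac_excitatory * N)
  sts <- spike_train_set(lapply(spikes, sort), region = "synthetic",
                         excitatory = exc,
                         t_start = min(sch$start), t_end = max(sch$end))
  down <- if (length(down_s)) interval_set(down_s, down_e, "DOWN")
          else interval_set(numeric(0), numeric(0), "DOWN")
  list(spikes = sts, hypnogram = sch, down = down, rates = rates)
}

# Persistent-activity constraint: cortical ensembles in Wake, REM and UP
# states essentially never fall silent for the OFF-period threshold, while
# independent Poisson trains do by chance. Any population gap of at least
# max_gap inside a firing segment (or half that at its edges) is broken by
# injecting single spikes from randomly chosen neurons.
fill_population_gaps <- function(seg, a, b, max_gap = 0.045) {
  merged <- sort(unlist(seg, use.names = FALSE))
  pts <- c(a, merged, b)
  gaps <- diff(pts)
  thr <- c(max_gap / 2, rep(max_gap, max(0L, length(gaps) - 2L)), max_gap / 2)
  if (length(gaps) == 1L) thr <- max_gap / 2
  for (i in which(gaps >= thr)) {
    k <- ceiling(gaps[i] / (if (i == 1L || i == length(gaps)) max_gap / 2
                            else max_gap)) - 1L
    if (k < 1L) next
    new_t <- pts[i] + seq_len(k) * gaps[i] / (k + 1)
    who <- sample.int(length(seg), k, replace = TRUE)
    for (j in seq_len(k)) seg[[who[j]]] <- c(seg[[who[j]]], new_t[j])
  }
  seg
}

# homogeneous Poisson spikes on [a, b)
poisson_train <- function(rate, a, b) {
  n <- stats::rpois(1L, rate * (b - a))
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, a, b))
}

# alternating UP/DOWN tiling of one SWS epoch, starting with UP
sws_periods <- function(a, b, spec) {
  start <- numeric(0); end <- numeric(0); up <- logical(0)
  t <- a; is_up <- TRUE
  while (t < b - 1e-9) {
    d <- if (is_up) stats::runif(1, spec$up_range[1], spec$up_range[2])
         else stats::runif(1, spec$down_range[1], spec$down_range[2])
    e <- min(t + d, b)
    start <- c(start, t); end <- c(end, e); up <- c(up, is_up)
    t <- e; is_up <- !is_up
  }
  data.frame(start = start, end = end, up = up)
}

#' Interval-set overlap (Jaccard index)
#'
#' Total length of the intersection divided by total length of the union of
#' two interval sets; used to score detected against planted DOWN periods.
#'
#' @param a,b `interval_set`s (data frames with `start`, `end`).
#' @return Numeric in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  grid <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(grid) < 2L) return(if (nrow(a) == 0 && nrow(b) == 0) 1 else 0)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  len <- diff(grid)
  in_a <- in_intervals(mid, a$start, a$end)
  in_b <- in_intervals(mid, b$start, b$end)
  inter <- sum(len[in_a & in_b])
  uni <- sum(len[in_a | in_b])
  if (uni == 0) 1 else inter / uni
}
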