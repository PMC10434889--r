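#' Branching simulator configuration
#'
#' Full parameterization of the critical branching network. Defaults follow
#' the study conditions: 50 units on an Erdos-Renyi graph with attachment
#' probability 0.03, Poisson noise rate `lambda = 0.014` per 1 ms step, and
#' (when silencing is on) 250 ms noise-silencing windows alternating within
#' a 500 ms cycle, i.e. delta-band alternation.
#'
#' @param n_units Number of units.
#' @param attach_p Erdos-Renyi link probability.
#' @param sigma Branching parameter; expected downstream spikes per spike
#'   (1 = critical).
#' @param lambda_noise Poisson noise intensity per step.
#' @param dt Step size (s); 0.001 fixes the 1 ms resolution.
#' @param n_steps Number of steps.
#' @param silenced_fraction Fraction of units whose noise is periodically
#'   silenced, in `[0, 1]`.
#' @param silence_duration Silence window length (s).
#' @param silence_period Silencing cycle length (s); must be `>=`
#'   `silence_duration`.
#' @param seed Integer RNG seed.
#' @return Object of class `branching_config`.
#' @export
branching_config <- function(n_units = 50L, attach_p = 0.03, sigma = 1.0,
                             lambda_noise = 0.014, dt = 0.001,
                             n_steps = 1e6, silenced_fraction = 0,
                             silence_duration = 0.250, silence_period = 0.500,
                             seed = 1L) {
  stopifnot(sigma >= 0, lambda_noise >= 0,
            silenced_fraction >= 0, silenced_fraction <= 1,
            silence_duration <= silence_period, n_units >= 2L)
  structure(list(n_units = as.integer(n_units), attach_p = attach_p,
                 sigma = sigma, lambda_noise = lambda_noise, dt = dt,
                 n_steps = as.integer(n_steps),
                 silenced_fraction = silenced_fraction,
                 silence_duration = silence_duration,
                 silence_period = silence_period, seed = as.integer(seed)),
            class = "branching_config")
}

#' Erdos-Renyi network topology
#'
#' Undirected simple graph in which each unordered pair of units is linked
#' independently with probability `attach_p`.
#'
#' @param n_units Number of units.
#' @param attach_p Link probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Object of class `network_topology`: list with the 0/1
#'   `adjacency` matrix and `mean_degree`.
#' @export
build_network <- function(n_units, attach_p, seed = NULL) {
  stopifnot(n_units >= 2L, attach_p >= 0, attach_p <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n_units, attach_p, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  mode(A) <- "numeric"
  md <- mean(rowSums(A))
  if (md == 0)
    warning("network has no edges; spike propagation is impossible")
  structure(list(adjacency = A, mean_degree = md, n_units = n_units),
            class = "network_topology")
}

#' Simulate the critical branching network
#'
#' Probabilistic cellular automaton at 1 ms resolution. Each unit is
#' resting, firing, or refractory. A resting unit fires at step `t` when
#' (a) any neighbour that fired at `t - 1` succeeds in an independent
#' Bernoulli attempt with `P_prop = sigma / <k>` (`<k>` the realized mean
#' degree, `P_prop` clamped to 1 with a warning), or (b) its own Poisson
#' noise fires, with probability `1 - exp(-lambda)`, unless the unit's
#' noise is silenced in the current window. A firing unit is refractory for
#' exactly one step, then resting. Silencing suppresses only the noisy
#' drive, never propagation; the silenced unit set is drawn once per
#' simulation.
#'
#' @param cfg A [branching_config()].
#' @param topo A [build_network()] topology; built from `cfg` when `NULL`.
#' @param init_fire Optional integer vector of units forced to fire at the
#'   first step (used to probe avalanche die-out with `lambda_noise = 0`).
#' @return A `spike_train_set` (units `u1 ... uN`, times in seconds) with
#'   the realized config and topology attached as attributes.
#' @export
simulate_branching <- function(cfg, topo = NULL, init_fire = NULL) {
  stopifnot(inherits(cfg, "branching_config"))
  set.seed(cfg$seed)
  if (is.null(topo)) topo <- build_network(cfg$n_units, cfg$attach_p)
  N <- cfg$n_units
  A <- topo$adjacency
  p_prop <- if (topo$mean_degree > 0) cfg$sigma / topo$mean_degree else 0
  if (p_prop > 1) {
    warning("sigma exceeds mean degree; clamping propagation probability to 1")
    p_prop <- 1
  }
  p_noise <- 1 - exp(-cfg$lambda_noise)
  n_sil <- round(cfg$silenced_fraction * N)
  silenced <- logical(N)
  if (n_sil > 0) silenced[sample.int(N, n_sil)] <- TRUE
  dur_steps <- round(cfg$silence_duration / cfg$dt)
  per_steps <- max(1L, round(cfg$silence_period / cfg$dt))

  cap <- 1048576L
  sp_t <- integer(cap); sp_u <- integer(cap); n_sp <- 0L
  fired <- logical(N)
  if (!is.null(init_fire)) fired[init_fire] <- TRUE
  if (any(fired)) {
    k <- sum(fired)
    sp_t[seq_len(k)] <- 1L; sp_u[seq_len(k)] <- which(fired); n_sp <- k
  }
  log1m_pp <- log1p(-min(p_prop, 1 - 1e-15))
  for (t in seq.int(2L, cfg$n_steps)) {
    if (p_noise == 0 && !any(fired)) break  # activity extinct, nothing can restart it
    # units that fired at t-1 are refractory at t; all others are resting
    resting <- !fired
    # combined firing probability: 1 - (1-p_prop)^m * (1-p_noise * noise_on)
    if (any(fired)) {
      m <- as.vector(A %*% fired)
      p_branch <- -expm1(m * log1m_pp)
    } else p_branch <- 0
    noise_on <- if (n_sil > 0 && ((t - 1L) %% per_steps) < dur_steps)
      !silenced else TRUE
    p_fire <- 1 - (1 - p_branch) * (1 - p_noise * noise_on)
    new_fired <- resting & (stats::runif(N) < p_fire)
    fired <- new_fired
    k <- sum(new_fired)
    if (k > 0L) {
      if (n_sp + k > cap) {
        cap <- cap * 2L
        sp_t <- c(sp_t, integer(cap - length(sp_t)))
        sp_u <- c(sp_u, integer(cap - length(sp_u)))
      }
      sp_t[(n_sp + 1L):(n_sp + k)] <- t
      sp_u[(n_sp + 1L):(n_sp + k)] <- which(new_fired)
      n_sp <- n_sp + k
    }
  }
  sp_t <- sp_t[seq_len(n_sp)]; sp_u <- sp_u[seq_len(n_sp)]
  ids <- sprintf("u%d", seq_len(N))
  spikes <- split((sp_t - 1L) * cfg$dt, factor(sp_u, levels = seq_len(N)))
  names(spikes) <- ids
  out <- spike_train_set(spikes, region = "model", excitatory = TRUE,
                         t_start = 0, t_end = cfg$n_steps * cfg$dt)
  attr(out, "config") <- cfg
  attr(out, "topology") <- topo
  attr(out, "silenced_units") <- which(silenced)
  out
}

#' Windowed RQA of a branching simulation
#'
#' Bins the simulated raster at `bin_width`, sets the tolerance to 1 SD of
#' the summed counts of the supplied baseline trajectory (the model analog
#' of the wakefulness-derived epsilon; the run itself when `baseline` is
#' `NULL`), and returns windowed RQA metrics.
#'
#' @param sim A `spike_train_set` from [simulate_branching()].
#' @param bin_width Bin width (s), default 0.05.
#' @param window_len RQA window (s), default 10.
#' @param baseline Optional baseline `spike_train_set` providing epsilon.
#' @return Data frame as from [windowed_rqa()], with attribute `epsilon`.
#' @export
branching_rqa <- function(sim, bin_width = 0.05, window_len = 10,
                          baseline = NULL) {
  traj <- bin_population(sim, bin_width)
  eps_src <- if (is.null(baseline)) traj else bin_population(baseline, bin_width)
  eps <- pop_sd(rowSums(eps_src$counts))
  out <- windowed_rqa(traj, eps, window_len)
  attr(out, "epsilon") <- eps
  out
}

#' Silencing-sweep of RQA differences
#'
#' For each silenced fraction, simulates `n_rep` pairs of runs (baseline
#' without silencing, silenced run; matched seeds) and reports the mean and
#' SD across repetitions of the per-metric difference silenced - baseline.
#' Epsilon always comes from the baseline run of the pair. When an
#' experimental `reference` difference is supplied, the smallest swept
#' fraction whose mean difference reaches it is reported per metric.
#'
#' @param cfg A [branching_config()]; its `silenced_fraction` is ignored.
#' @param fractions Numeric vector of silenced fractions to sweep.
#' @param n_rep Repetitions per fraction (default 5).
#' @param reference Optional named numeric vector of target differences
#'   (names among RR, DET, LAM, TT, DIV).
#' @param bin_width,window_len Passed to [branching_rqa()].
#' @return Data frame with one row per (fraction, metric): `fraction`,
#'   `metric`, `delta_mean`, `delta_sd`; attribute `crossings` when
#'   `reference` was given.
#' @export
delta_rqa_curve <- function(cfg, fractions, n_rep = 5L, reference = NULL,
                            bin_width = 0.05, window_len = 10) {
  if (!length(fractions)) stop("empty fraction list")
  metrics <- c("RR", "DET", "LAM", "TT", "DIV")
  rows <- list()
  for (f in fractions) {
    deltas <- matrix(NA_real_, n_rep, length(metrics),
                     dimnames = list(NULL, metrics))
    for (r in seq_len(n_rep)) {
      seed_r <- cfg$seed + 1000L * r
      base_cfg <- cfg; base_cfg$silenced_fraction <- 0; base_cfg$seed <- seed_r
      sil_cfg <- cfg; sil_cfg$silenced_fraction <- f; sil_cfg$seed <- seed_r
      topo <- build_network(cfg$n_units, cfg$attach_p, seed = seed_r)
      base <- simulate_branching(base_cfg, topo)
      sil <- simulate_branching(sil_cfg, topo)
      mb <- colMeans(branching_rqa(base, bin_width, window_len)[, metrics])
      ms <- colMeans(branching_rqa(sil, bin_width, window_len,
                                   baseline = base)[, metrics])
      deltas[r, ] <- ms - mb
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, metric = metrics,
      delta_mean = colMeans(deltas), delta_sd = apply(deltas, 2L, stats::sd),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    cross <- vapply(names(reference), function(m) {
      sub <- out[out$metric == m, ]
      hit <- if (reference[[m]] >= 0) sub$fraction[sub$delta_mean >= reference[[m]]]
             else sub$fraction[sub$delta_mean <= reference[[m]]]
      if (length(hit)) min(hit) else NA_real_
    }, 0)
    attr(out, "crossings") <- cross
  }
  out
}
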