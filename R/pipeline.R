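#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled (n-1) standard deviation; |d| > 0.8 is conventionally large.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return Numeric d.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled SD; effect size undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Percentile bootstrap confidence interval
#'
#' @param values Numeric sample (>= 2 values).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param n_boot Number of resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return Length-2 numeric `(lo, hi)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000L,
                         level = 0.95, seed = NULL) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    statistic(sample(values, replace = TRUE)), 0)
  unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Compare windowed RQA across sleep-wake states
#'
#' For each session the tolerance epsilon is derived from Wake
#' ([wake_epsilon()]); each state's spikes are binned per epoch,
#' concatenated, and scored by windowed RQA; per-session means enter a
#' paired Friedman omnibus test across states, followed by pairwise paired
#' Wilcoxon signed-rank post-hoc tests with Benjamini-Hochberg correction
#' and Cohen's d effect sizes. With `up_only = TRUE` the SWS trajectory has
#' its DOWN bins removed first (detected by the chosen rule), probing
#' whether state differences survive on UP states alone.
#'
#' @param sessions List of sessions, each a list with `spikes`
#'   (`spike_train_set`) and `hypnogram` (e.g. from [gen_session()]).
#' @param bin_width,window_len RQA parameters (s).
#' @param up_only Remove SWS DOWN bins before windowing.
#' @param down_rule `"neocortex-off"` or `"hippocampus-fraction"` for the
#'   DOWN detection used by `up_only`.
#' @param states States to compare.
#' @return Object of class `comparison_report`: list with `per_window`
#'   (pooled windowed metrics), `per_session` (session x state means),
#'   `friedman` (per-metric omnibus), `posthoc` (pairwise adjusted
#'   p-values and Cohen's d), and the parameters.
#' @export
run_state_comparison <- function(sessions, bin_width = 0.05, window_len = 10,
                                 up_only = FALSE,
                                 down_rule = c("neocortex-off",
                                               "hippocampus-fraction"),
                                 states = c("Wake", "SWS", "REM")) {
  down_rule <- match.arg(down_rule)
  metrics <- c("RR", "DET", "LAM", "TT", "DIV")
  per_window <- list()
  per_session <- list()
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    have <- vapply(states, function(st) any(ses$hypnogram$state == st), TRUE)
    if (!all(have)) {
      warning("session ", s, " lacks state(s) ",
              paste(states[!have], collapse = ", "), "; excluded")
      next
    }
    eps <- wake_epsilon(ses$spikes, ses$hypnogram, bin_width)
    for (st in states) {
      traj <- state_trajectory(ses$spikes, ses$hypnogram, st, bin_width)
      if (up_only && st == "SWS") {
        down <- if (down_rule == "neocortex-off")
          intervals_to_down_series(detect_off_periods(ses$spikes), traj)
        else detect_fraction_down(traj)
        traj <- exclude_down_bins(traj, down)
      }
      wm <- suppressWarnings(windowed_rqa(traj, eps, window_len))
      if (nrow(wm) == 0L) next
      wm$session <- s; wm$state <- st
      per_window[[length(per_window) + 1L]] <- wm
      per_session[[length(per_session) + 1L]] <-
        data.frame(session = s, state = st, t(colMeans(wm[, metrics])))
    }
  }
  pw <- do.call(rbind, per_window)
  ps <- do.call(rbind, per_session)
  if (is.null(ps) || length(unique(ps$session)) < 3L)
    stop("need at least 3 complete sessions for the paired design")
  complete <- names(which(table(ps$session) == length(states)))
  ps <- ps[ps$session %in% as.integer(complete), ]

  friedman <- lapply(metrics, function(m) {
    mat <- stats::reshape(ps[, c("session", "state", m)], direction = "wide",
                          idvar = "session", timevar = "state")
    mat <- as.matrix(mat[, -1])
    ft <- stats::friedman.test(mat)
    data.frame(metric = m, chisq = unname(ft$statistic),
               df = unname(ft$parameter), p_value = ft$p.value)
  })
  friedman <- do.call(rbind, friedman)

  pairs <- utils::combn(states, 2, simplify = FALSE)
  posthoc <- list()
  for (m in metrics) {
    raw <- vapply(pairs, function(pr) {
      a <- ps[ps$state == pr[1], m][order(ps[ps$state == pr[1], "session"])]
      b <- ps[ps$state == pr[2], m][order(ps[ps$state == pr[2], "session"])]
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
    }, 0)
    ds <- vapply(pairs, function(pr)
      cohens_d(pw[pw$state == pr[1], m], pw[pw$state == pr[2], m]), 0)
    posthoc[[m]] <- data.frame(
      metric = m,
      pair = vapply(pairs, paste, "", collapse = "-"),
      p_raw = raw, p_adj = stats::p.adjust(raw, method = "BH"),
      cohens_d = ds)
  }
  structure(list(per_window = pw, per_session = ps, friedman = friedman,
                 posthoc = do.call(rbind, posthoc),
                 params = list(bin_width = bin_width, window_len = window_len,
                               up_only = up_only, down_rule = down_rule,
                               states = states)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d sessions x %d states%s\n",
              length(unique(x$per_session$session)), length(x$params$states),
              if (x$params$up_only) " (UP-only SWS)" else ""))
  print(x$friedman, row.names = FALSE)
  invisible(x)
}

#' Tolerance and bin-width robustness sweep
#'
#' Recomputes per-state mean windowed RQA over a grid of tolerance factors
#' (multiples of the Wake SD, 0-4) and bin widths (20-200 ms), to check
#' that state orderings are not artifacts of the parameter choice.
#'
#' @param session A list with `spikes` and `hypnogram`.
#' @param eps_factors Multiples of the Wake-derived epsilon.
#' @param bin_widths Bin widths (s).
#' @param window_len RQA window (s).
#' @param states States to include.
#' @return Data frame with columns `eps_factor`, `bin_width`, `state`, and
#'   the mean RQA metrics.
#' @export
robustness_sweep <- function(session, eps_factors = 0:4,
                             bin_widths = c(0.02, 0.05, 0.1, 0.2),
                             window_len = 10, states = c("Wake", "SWS")) {
  metrics <- c("RR", "DET", "LAM", "TT", "DIV")
  rows <- list()
  for (bw in bin_widths) {
    eps1 <- wake_epsilon(session$spikes, session$hypnogram, bw)
    trajs <- lapply(states, function(st)
      state_trajectory(session$spikes, session$hypnogram, st, bw))
    for (ef in eps_factors) {
      for (i in seq_along(states)) {
        wm <- suppressWarnings(windowed_rqa(trajs[[i]], ef * eps1, window_len))
        if (nrow(wm) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          eps_factor = ef, bin_width = bw, state = states[i],
          t(colMeans(wm[, metrics])))
      }
    }
  }
  do.call(rbind, rows)
}

#' Neuron-count dependence of state differences
#'
#' Randomly subsamples the population at several sizes, recomputes
#' per-state mean RQA, and regresses the absolute SWS-Wake difference on
#' the subsample size. A positive slope indicates the complexity reduction
#' is a population-level phenomenon that grows with ensemble size.
#'
#' @param session A list with `spikes` and `hypnogram`.
#' @param sizes Integer subsample sizes (each `<=` number of neurons).
#' @param n_rep Random subsets per size.
#' @param seed Integer seed.
#' @param bin_width,window_len RQA parameters.
#' @return List with `table` (size, rep, metric differences) and `slopes`
#'   (per-metric linear-regression slope and p-value).
#' @export
neuron_count_dependence <- function(session, sizes, n_rep = 3L, seed = 1L,
                                    bin_width = 0.05, window_len = 10) {
  N <- n_neurons(session$spikes)
  if (any(sizes > N)) stop("subsample size exceeds population size")
  set.seed(seed)
  metrics <- c("RR", "DET", "LAM", "TT", "DIV")
  rows <- list()
  for (sz in sizes) for (r in seq_len(n_rep)) {
    keep <- sample.int(N, sz)
    sub <- session$spikes
    sub$spikes <- sub$spikes[keep]
    sub$neuron_ids <- sub$neuron_ids[keep]
    sub$excitatory <- sub$excitatory[keep]
    eps <- wake_epsilon(sub, session$hypnogram, bin_width)
    means <- lapply(c("Wake", "SWS"), function(st) {
      wm <- windowed_rqa(state_trajectory(sub, session$hypnogram, st, bin_width),
                         eps, window_len)
      colMeans(wm[, metrics])
    })
    rows[[length(rows) + 1L]] <- data.frame(
      size = sz, rep = r, t(abs(means[[2]] - means[[1]])))
  }
  tab <- do.call(rbind, rows)
  slopes <- do.call(rbind, lapply(metrics, function(m) {
    if (length(unique(tab$size)) < 2L || nrow(tab) < 3L)
      return(data.frame(metric = m, slope = NA_real_, p_value = NA_real_))
    fit <- summary(stats::lm(tab[[m]] ~ tab$size))
    data.frame(metric = m, slope = fit$coefficients[2, 1],
               p_value = fit$coefficients[2, 4])
  }))
  list(table = tab, slopes = slopes)
}
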