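#' Detect neocortical OFF periods
#'
#' An OFF period is a maximal gap in the merged population spike train whose
#' duration lies within `[min_dur, max_dur]` (defaults 50 ms and 1250 ms).
#' The interval spans from the last spike before the silence to the first
#' spike after it.
#'
#' @param x A `spike_train_set` (or numeric vector of merged spike times).
#' @param min_dur,max_dur Duration bounds in seconds.
#' @return An `interval_set` labelled `"OFF"`.
#' @export
detect_off_periods <- function(x, min_dur = 0.050, max_dur = 1.250) {
  t <- if (inherits(x, "spike_train_set")) merged_spikes(x) else sort(as.numeric(x))
  if (length(t) == 0L) stop("population silence undefined for an empty spike set")
  if (length(t) < 2L)
    return(interval_set(numeric(0), numeric(0), "OFF"))
  gaps <- diff(t)
  keep <- gaps >= min_dur - 1e-12 & gaps <= max_dur + 1e-12
  interval_set(t[-length(t)][keep], t[-1][keep], "OFF")
}

#' Detect ON periods between OFF periods
#'
#' ON periods are the segments between consecutive OFF periods that contain
#' at least `min_spikes` population spikes and last between `min_dur` and
#' `max_dur` (defaults: 10 spikes, 200-4000 ms). Segment bounds are the
#' delimiting spikes of the flanking OFF periods; spike counting is closed
#' on both ends.
#'
#' @param x A `spike_train_set`.
#' @param off An `interval_set` of OFF periods from the same session.
#' @param min_spikes Minimum total population spikes.
#' @param min_dur,max_dur Duration bounds in seconds.
#' @return An `interval_set` labelled `"ON"`.
#' @export
detect_on_periods <- function(x, off, min_spikes = 10L, min_dur = 0.200,
                              max_dur = 4.000) {
  t <- merged_spikes(x)
  if (nrow(off) < 2L) return(interval_set(numeric(0), numeric(0), "ON"))
  seg_start <- off$end[-nrow(off)]
  seg_end <- off$start[-1]
  dur <- seg_end - seg_start
  n_sp <- vapply(seq_along(seg_start), function(i)
    sum(t >= seg_start[i] - 1e-12 & t <= seg_end[i] + 1e-12), 0L)
  keep <- dur >= min_dur - 1e-12 & dur <= max_dur + 1e-12 & n_sp >= min_spikes
  interval_set(seg_start[keep], seg_end[keep], "ON")
}

#' Fraction-rule DOWN-state series (hippocampus)
#'
#' Marks a bin as DOWN when strictly fewer than `fraction` of the recorded
#' neurons fired in it (default 10%), the rule for structures that keep
#' minimal firing during DOWN states.
#'
#' @param traj A `population_trajectory`.
#' @param fraction Active-neuron fraction threshold in `(0, 1)`.
#' @return Object of class `down_state_series`: integer 0/1 vector of
#'   length T with attributes `rule`, `bin_starts`, `bin_width`.
#' @export
detect_fraction_down <- function(traj, fraction = 0.10) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- ncol(traj$counts)
  if (n < 10L) warning("fraction rule is unreliable with fewer than 10 neurons")
  active <- rowSums(traj$counts >= 1L)
  down_state_series(as.integer(active / n < fraction), traj,
                    rule = "hippocampus-fraction")
}

down_state_series <- function(ind, traj, rule) {
  structure(as.integer(ind), rule = rule, bin_starts = traj$bin_starts,
            bin_width = traj$bin_width, class = "down_state_series")
}

#' Rasterize OFF intervals onto trajectory bins
#'
#' A bin is marked DOWN when at least half of it is covered by an OFF
#' interval (majority rule; state boundaries need not align with bins).
#'
#' @param off An `interval_set` (OFF or DOWN).
#' @param traj The `population_trajectory` providing the bin grid.
#' @return A `down_state_series` aligned with `traj`.
#' @export
intervals_to_down_series <- function(off, traj) {
  bw <- traj$bin_width
  cover <- vapply(traj$bin_starts, function(b0) {
    b1 <- b0 + bw
    sum(pmax(0, pmin(off$end, b1) - pmax(off$start, b0)))
  }, 0)
  down_state_series(as.integer(cover >= bw / 2), traj, rule = "neocortex-off")
}

#' Convert a DOWN series back to intervals
#'
#' Maximal runs of DOWN bins become intervals on the bin grid; the inverse
#' of [intervals_to_down_series()] up to one bin of quantization.
#'
#' @param down A `down_state_series`.
#' @return An `interval_set` labelled `"DOWN"`.
#' @export
down_series_to_intervals <- function(down) {
  r <- rle(as.integer(down) == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(interval_set(numeric(0), numeric(0), "DOWN"))
  bs <- attr(down, "bin_starts"); bw <- attr(down, "bin_width")
  interval_set(bs[starts[keep]], bs[ends[keep]] + bw, "DOWN")
}

#' Point-biserial correlation of DOWN states with recurrences
#'
#' Correlates the binary per-bin DOWN indicator with the per-bin recurrence
#' count profile (see [recurrence_time_profile()]). The point-biserial
#' coefficient is the Pearson correlation with the binary variable; the
#' p-value comes from the t distribution with n - 2 degrees of freedom.
#'
#' @param down A `down_state_series` (or 0/1 vector).
#' @param profile Numeric vector of per-bin recurrence counts, same length.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_down_recurrence <- function(down, profile) {
  d <- as.numeric(down)
  if (length(d) != length(profile)) stop("series lengths differ")
  if (length(unique(d)) < 2L) stop("DOWN series has a single class; correlation undefined")
  if (pop_sd(profile) == 0) stop("constant recurrence profile; correlation undefined")
  n <- length(d)
  m1 <- mean(profile[d == 1]); m0 <- mean(profile[d == 0])
  n1 <- sum(d == 1); n0 <- n - n1
  r <- (m1 - m0) / pop_sd(profile) * sqrt(n1 * n0 / n^2)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' UP-only trajectory
#'
#' Removes DOWN bins and concatenates the remaining bins, yielding a
#' time-compressed trajectory of the population UP states. Downstream
#' windows may span removed time; the result is flagged with attribute
#' `time_compressed = TRUE`.
#'
#' @param traj A `population_trajectory`.
#' @param down A `down_state_series` aligned with `traj`.
#' @return A `population_trajectory` of the non-DOWN bins.
#' @export
exclude_down_bins <- function(traj, down) {
  d <- as.integer(down)
  if (length(d) != nrow(traj$counts)) stop("DOWN series not aligned with trajectory")
  if (all(d == 1L)) stop("all bins are DOWN; nothing left")
  keep <- d == 0L
  out <- population_trajectory(traj$counts[keep, , drop = FALSE], traj$bin_width,
                               bin_starts = traj$bin_starts[keep],
                               neuron_ids = traj$neuron_ids)
  attr(out, "time_compressed") <- TRUE
  out
}
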