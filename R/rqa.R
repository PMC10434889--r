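#' Recurrence tolerance from wakefulness
#'
#' The recurrence tolerance epsilon is set to the standard deviation across
#' time of the neuron-summed firing counts over all Wake bins of the
#' session. The population (divide-by-n) standard deviation is used.
#'
#' @param x A `spike_train_set`.
#' @param hyp A [hypnogram()] containing Wake epochs.
#' @param bin_width Bin width in seconds (default 0.05).
#' @return Numeric tolerance in count units.
#' @export
wake_epsilon <- function(x, hyp, bin_width = 0.05) {
  traj <- tryCatch(state_trajectory(x, hyp, "Wake", bin_width),
                   error = function(e) stop("epsilon undefined: ", conditionMessage(e)))
  pop_sd(rowSums(traj$counts))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Recurrence matrix of a population trajectory
#'
#' Marks bin pairs whose count vectors are within tolerance:
#' `R(i,j) = 1` iff `||x(t_i) - x(t_j)|| <= epsilon` (inclusive, so
#' `epsilon = 0` still marks exact firing-pattern repeats).
#'
#' @param traj A `population_trajectory`.
#' @param epsilon Tolerance (count units), `>= 0`.
#' @param norm Distance norm: `"euclidean"` (default) or `"chebyshev"`.
#' @param window_id Optional identifier carried through to results.
#' @return Object of class `recurrence_plot`: list with the logical T x T
#'   matrix `R`, `epsilon`, `norm`, `window_id`, `bin_width`.
#' @export
recurrence_matrix <- function(traj, epsilon, norm = c("euclidean", "chebyshev"),
                              window_id = NA) {
  stopifnot(inherits(traj, "population_trajectory"), epsilon >= 0)
  norm <- match.arg(norm)
  cc <- traj$counts
  if (nrow(cc) < 2L) stop("trajectory must have at least 2 bins")
  if (any(!is.finite(cc))) stop("non-finite counts")
  method <- if (norm == "euclidean") "euclidean" else "maximum"
  d <- as.matrix(stats::dist(cc, method = method))
  structure(list(R = d <= epsilon + 1e-12, epsilon = epsilon, norm = norm,
                 window_id = window_id, bin_width = traj$bin_width),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("recurrence_plot: %d x %d, epsilon = %.4g (%s), density %.4f\n",
              nrow(x$R), ncol(x$R), x$epsilon, x$norm, mean(x$R)))
  invisible(x)
}

# run lengths of TRUE values in a logical vector
true_runs <- function(v) {
  if (!length(v)) return(integer(0))
  r <- rle(v)
  r$lengths[r$values]
}

# lengths of diagonal TRUE runs over both triangles, identity excluded
diagonal_runs <- function(R) {
  n <- nrow(R)
  out <- vector("list", n - 1L)
  for (d in seq_len(n - 1L)) {
    i <- seq_len(n - d)
    out[[d]] <- true_runs(R[cbind(i, i + d)])
  }
  runs <- unlist(out, use.names = FALSE)
  c(runs, runs)  # lower triangle mirrors the upper by symmetry
}

# lengths of vertical TRUE runs, identity included
vertical_runs <- function(R) {
  unlist(lapply(seq_len(ncol(R)), function(j) true_runs(R[, j])),
         use.names = FALSE)
}

#' Recurrence quantification metrics
#'
#' Computes the five standard measures from a recurrence plot:
#' \describe{
#'   \item{RR}{recurrence rate, density of recurrent points including the
#'     identity line.}
#'   \item{DET}{fraction of off-identity recurrent points lying on diagonal
#'     lines of length `>= l_min` (identity line excluded from numerator and
#'     denominator, a Theiler window of 1).}
#'   \item{LAM}{fraction of recurrent points lying on vertical lines of
#'     length `>= v_min`; vertical structures crossing the identity are
#'     genuine trapping and are kept.}
#'   \item{TT}{trapping time, the mean length of vertical lines
#'     `>= v_min`; 0 when none exist.}
#'   \item{DIV}{divergence, `1 / L_max` with `L_max` the longest diagonal
#'     line excluding the identity; isolated points only gives `DIV = 1`.}
#' }
#'
#' @param rp A `recurrence_plot`, or a logical/0-1 square symmetric matrix.
#' @param l_min,v_min Minimum diagonal / vertical line lengths (default 2).
#' @param include_loi_det Include the identity line in DET (default `FALSE`).
#' @return Object of class `rqa_metrics`: list with `RR`, `DET`, `LAM`,
#'   `TT`, `DIV`, `L_max`, the line-length tables `diagonal_hist` and
#'   `vertical_hist`, and the parameters used.
#' @export
rqa_metrics <- function(rp, l_min = 2L, v_min = 2L, include_loi_det = FALSE) {
  R <- if (inherits(rp, "recurrence_plot")) rp$R else rp
  if (is.numeric(R)) R <- R > 0
  if (!is.matrix(R) || nrow(R) != ncol(R) || nrow(R) < 1L)
    stop("recurrence matrix must be a non-empty square matrix")
  if (l_min < 2L || v_min < 2L) stop("l_min and v_min must be >= 2")
  n <- nrow(R)
  n_points <- sum(R)
  RR <- n_points / n^2

  d_runs <- diagonal_runs(R)
  if (include_loi_det) d_runs <- c(d_runs, true_runs(R[cbind(1:n, 1:n)]))
  d_tot <- sum(d_runs)
  DET <- if (d_tot > 0) sum(d_runs[d_runs >= l_min]) / d_tot else 0

  v_runs <- vertical_runs(R)
  v_sel <- v_runs[v_runs >= v_min]
  LAM <- if (n_points > 0) sum(v_sel) / n_points else 0
  TT <- if (length(v_sel)) mean(v_sel) else 0

  off_runs <- diagonal_runs(R)
  L_max <- if (length(off_runs)) max(off_runs) else 1L
  structure(list(RR = RR, DET = DET, LAM = LAM, TT = TT, DIV = 1 / L_max,
                 L_max = L_max,
                 diagonal_hist = table(d_runs), vertical_hist = table(v_runs),
                 l_min = l_min, v_min = v_min),
            class = "rqa_metrics")
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf("RQA: RR=%.4f DET=%.4f LAM=%.4f TT=%.3f DIV=%.4f (Lmax=%d)\n",
              x$RR, x$DET, x$LAM, x$TT, x$DIV, x$L_max))
  invisible(x)
}

#' Windowed recurrence quantification
#'
#' Splits a trajectory into non-overlapping windows (default 10 s, i.e.
#' 200 bins at 50 ms), builds a recurrence plot per window at a common
#' tolerance, and returns one row of metrics per window. The incomplete
#' trailing window is dropped.
#'
#' @inheritParams recurrence_matrix
#' @param window_len Window length in seconds.
#' @param l_min,v_min Minimum line lengths.
#' @return Data frame with columns `window`, `t_start`, `RR`, `DET`, `LAM`,
#'   `TT`, `DIV`; zero rows (with a warning) when the trajectory is shorter
#'   than one window.
#' @export
windowed_rqa <- function(traj, epsilon, window_len = 10,
                         norm = "euclidean", l_min = 2L, v_min = 2L) {
  w_bins <- floor(window_len / traj$bin_width + 1e-9)
  if (w_bins < 2L) stop("window_len must cover at least 2 bins")
  n_win <- nrow(traj$counts) %/% w_bins
  if (n_win < 1L) {
    warning("trajectory shorter than one window; returning no metrics")
    return(data.frame(window = integer(0), t_start = numeric(0), RR = numeric(0),
                      DET = numeric(0), LAM = numeric(0), TT = numeric(0),
                      DIV = numeric(0)))
  }
  rows <- lapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * w_bins + 1L):(w * w_bins)
    sub <- population_trajectory(traj$counts[idx, , drop = FALSE],
                                 traj$bin_width,
                                 bin_starts = traj$bin_starts[idx],
                                 neuron_ids = traj$neuron_ids)
    m <- rqa_metrics(recurrence_matrix(sub, epsilon, norm, window_id = w),
                     l_min, v_min)
    data.frame(window = w, t_start = traj$bin_starts[idx[1]], RR = m$RR,
               DET = m$DET, LAM = m$LAM, TT = m$TT, DIV = m$DIV)
  })
  do.call(rbind, rows)
}

#' Recurrences per time bin
#'
#' Column sums of the recurrence matrix: how often each time bin recurs
#' with any other (including itself). Aligned with DOWN-state series to
#' test what drives recurrences.
#'
#' @param rp A `recurrence_plot`.
#' @return Numeric vector of length T.
#' @export
recurrence_time_profile <- function(rp) {
  R <- if (inherits(rp, "recurrence_plot")) rp$R else rp
  colSums(R)
}
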