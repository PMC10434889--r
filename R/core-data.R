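#' Construct a spike train set
#'
#' Container for the simultaneously recorded spike trains of a neuronal
#' population. Spike times are in seconds on a common session clock.
#'
#' @param spikes Named list of numeric vectors, one per neuron, each the
#'   sorted spike times (s) of that neuron. Names are the neuron ids.
#' @param region Label for the recorded structure, e.g. `"neocortex"` or
#'   `"hippocampus"`.
#' @param excitatory Logical vector (recycled if length 1) flagging putative
#'   excitatory units; used by [build_slfp()].
#' @param t_start,t_end Recording bounds (s). Inferred from the data when
#'   `NULL` (0 and the last spike time).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, region = "neocortex", excitatory = TRUE,
                            t_start = NULL, t_end = NULL) {
  if (!is.list(spikes)) stop("`spikes` must be a list of numeric vectors")
  ids <- names(spikes)
  if (length(spikes) > 0L && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    stop("neuron ids (names of `spikes`) must be unique and non-empty")
  spikes <- lapply(spikes, function(x) {
    x <- as.numeric(x)
    if (anyNA(x) || any(!is.finite(x))) stop("non-finite spike times")
    if (is.unsorted(x)) x <- sort(x)
    x
  })
  all_t <- unlist(spikes, use.names = FALSE)
  if (is.null(t_start)) t_start <- if (length(all_t)) min(0, min(all_t)) else 0
  if (is.null(t_end)) t_end <- if (length(all_t)) max(all_t) else 0
  if (length(all_t) && (min(all_t) < t_start || max(all_t) > t_end))
    stop("spike times outside [t_start, t_end]")
  excitatory <- rep_len(as.logical(excitatory), length(spikes))
  names(excitatory) <- ids
  structure(list(spikes = spikes, neuron_ids = ids, region = region,
                 excitatory = excitatory,
                 t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf("spike_train_set: %d neurons, %d spikes, [%.3f, %.3f] s, region %s\n",
              length(x$spikes), n_sp, x$t_start, x$t_end, x$region))
  invisible(x)
}

#' Number of neurons / total spikes in a spike train set
#' @param x A `spike_train_set`.
#' @return Integer count.
#' @export
n_neurons <- function(x) length(x$spikes)

#' @rdname n_neurons
#' @export
n_spikes <- function(x) sum(lengths(x$spikes))

#' Merged population spike train
#'
#' All spike times of the population pooled and sorted; the basis of
#' OFF-period and avalanche detection.
#'
#' @param x A `spike_train_set`.
#' @return Sorted numeric vector of spike times (s).
#' @export
merged_spikes <- function(x) sort(unlist(x$spikes, use.names = FALSE))

#' Construct a hypnogram
#'
#' Sequence of scored sleep-wake epochs (Wake, SWS, REM) on the session
#' clock. Intervals are half-open `[start, end)`, must not overlap, and are
#' stored sorted by start.
#'
#' @param start,end Numeric vectors of epoch bounds (s).
#' @param state Character vector of state labels; one of `"Wake"`, `"SWS"`,
#'   `"REM"`.
#' @return An object of class `hypnogram` (a data frame).
#' @export
hypnogram <- function(start, end, state) {
  start <- as.numeric(start); end <- as.numeric(end); state <- as.character(state)
  if (length(start) != length(end) || length(start) != length(state))
    stop("start, end, state must have equal length")
  if (any(end <= start)) stop("hypnogram epochs must have end > start")
  bad <- setdiff(unique(state), c("Wake", "SWS", "REM"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  o <- order(start)
  start <- start[o]; end <- end[o]; state <- state[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)] - 1e-12))
    stop("hypnogram epochs overlap")
  structure(data.frame(start = start, end = end, state = state,
                       stringsAsFactors = FALSE),
            class = c("hypnogram", "data.frame"))
}

#' Construct a labelled interval set
#'
#' Non-overlapping sorted time intervals sharing one label (OFF, DOWN, UP,
#' ON), e.g. detected OFF periods.
#'
#' @param start,end Numeric vectors of interval bounds (s).
#' @param label One of `"OFF"`, `"DOWN"`, `"UP"`, `"ON"`.
#' @return An object of class `interval_set` (a data frame with a `label`
#'   attribute).
#' @export
interval_set <- function(start, end, label = "OFF") {
  start <- as.numeric(start); end <- as.numeric(end)
  label <- match.arg(label, c("OFF", "DOWN", "UP", "ON"))
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (any(end <= start)) stop("intervals must have end > start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)] - 1e-12))
    stop("intervals overlap")
  structure(data.frame(start = start, end = end), label = label,
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set [%s]: %d intervals, total %.3f s\n",
              attr(x, "label"), nrow(x), sum(x$end - x$start)))
  invisible(x)
}

# -- file I/O -----------------------------------------------------------------

#' Read / write spike tables
#'
#' The on-disk dialect is a TSV with header columns `neuron_id` and
#' `time_s`, one spike per row. Metadata (region, per-neuron excitatory
#' flags, recording bounds) lives in an optional key=value sidecar file
#' `<path>.meta` with lines `region=...`, `t_start=...`, `t_end=...`,
#' `inhibitory=id1,id2,...`.
#'
#' @param path Path of the spike TSV.
#' @return `load_spikes()` returns a `spike_train_set`; `write_spikes()`
#'   returns `path` invisibly.
#' @export
load_spikes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c(neuron_id = "character"),
                           stringsAsFactors = FALSE)
  if (!all(c("neuron_id", "time_s") %in% names(tab)))
    stop("spike table must have columns neuron_id and time_s: ", path)
  tt <- suppressWarnings(as.numeric(tab$time_s))
  bad <- which(is.na(tt) | tt < 0)
  if (length(bad))
    stop(sprintf("malformed spike row at line %d of %s", bad[1] + 1L, path))
  meta <- read_sidecar(paste0(path, ".meta"))
  spikes <- split(tt, factor(tab$neuron_id, levels = unique(tab$neuron_id)))
  exc <- rep_len(TRUE, length(spikes))
  names(exc) <- names(spikes)
  if (!is.null(meta$inhibitory)) {
    inh <- strsplit(meta$inhibitory, ",", fixed = TRUE)[[1]]
    exc[names(exc) %in% inh] <- FALSE
  }
  spike_train_set(spikes,
                  region = if (is.null(meta$region)) "neocortex" else meta$region,
                  excitatory = exc,
                  t_start = if (is.null(meta$t_start)) NULL else as.numeric(meta$t_start),
                  t_end = if (is.null(meta$t_end)) NULL else as.numeric(meta$t_end))
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  out <- lapply(kv, function(x) trimws(x[2]))
  names(out) <- vapply(kv, function(x) trimws(x[1]), "")
  out
}

#' @rdname load_spikes
#' @param x A `spike_train_set` to write.
#' @export
write_spikes <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  tab <- data.frame(
    neuron_id = rep(x$neuron_ids, lengths(x$spikes)),
    time_s = sprintf("%.9f", unlist(x$spikes, use.names = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("region=%s", x$region),
            sprintf("t_start=%.9f", x$t_start),
            sprintf("t_end=%.9f", x$t_end))
  if (any(!x$excitatory))
    meta <- c(meta, sprintf("inhibitory=%s",
                            paste(x$neuron_ids[!x$excitatory], collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read / write hypnograms and interval sets
#'
#' Hypnograms are TSVs with columns `start_s`, `end_s`, `state`; interval
#' sets are BED-like TSVs with columns `start_s`, `end_s`, `label`.
#'
#' @param path File path.
#' @return `load_hypnogram()` a `hypnogram`; `load_intervals()` an
#'   `interval_set`.
#' @export
load_hypnogram <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  hypnogram(tab$start_s, tab$end_s, tab$state)
}

#' @rdname load_hypnogram
#' @param x Object to write.
#' @export
write_hypnogram <- function(x, path) {
  utils::write.table(data.frame(start_s = x$start, end_s = x$end, state = x$state),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname load_hypnogram
#' @export
load_intervals <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  interval_set(tab$start_s, tab$end_s, label = tab$label[1])
}

#' @rdname load_hypnogram
#' @export
write_intervals <- function(x, path) {
  utils::write.table(data.frame(start_s = x$start, end_s = x$end,
                                label = attr(x, "label")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- state restriction and binning -------------------------------------------

#' Restrict spikes to one sleep-wake state
#'
#' Keeps only spikes falling inside the hypnogram epochs of the requested
#' state; epoch bounds are half-open `[start, end)`.
#'
#' @param x A `spike_train_set`.
#' @param hyp A [hypnogram()].
#' @param state State label to keep.
#' @return A `spike_train_set` with the same neurons (possibly empty trains).
#' @export
restrict_to_state <- function(x, hyp, state) {
  stopifnot(inherits(x, "spike_train_set"), inherits(hyp, "hypnogram"))
  ep <- hyp[hyp$state == state, , drop = FALSE]
  if (nrow(ep) == 0L)
    warning("no epochs of state ", state, " in hypnogram; returning empty set")
  keep <- function(t) t[in_intervals(t, ep$start, ep$end)]
  out <- x
  out$spikes <- lapply(x$spikes, keep)
  out
}

# half-open membership t in [start_i, end_i) for any i; intervals sorted
in_intervals <- function(t, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(t)))
  i <- findInterval(t, start)
  i > 0L & t < end[pmax(i, 1L)]
}

#' Bin a population into a phase-space trajectory
#'
#' Counts spikes of each neuron in non-overlapping half-open bins
#' `[start + i*bin_width, start + (i+1)*bin_width)`. The trailing partial
#' bin is discarded. The resulting T x N count matrix is the population
#' trajectory: one point in N-dimensional phase space per time bin.
#'
#' @param x A `spike_train_set`.
#' @param bin_width Bin width in seconds (default 0.05, matching the minimum
#'   neocortical OFF-period duration).
#' @param window Length-2 numeric `(start, end)` in seconds; defaults to the
#'   recording bounds.
#' @return An object of class `population_trajectory` with elements
#'   `counts` (T x N integer matrix), `bin_width`, `bin_starts`,
#'   `neuron_ids`.
#' @export
bin_population <- function(x, bin_width = 0.05, window = NULL) {
  stopifnot(inherits(x, "spike_train_set"), bin_width > 0)
  if (is.null(window)) window <- c(x$t_start, x$t_end)
  n_bins <- floor((window[2] - window[1]) / bin_width + 1e-9)
  if (n_bins < 1L) stop("window shorter than one bin")
  counts <- vapply(x$spikes, function(t) {
    idx <- floor((t - window[1]) / bin_width) + 1L
    idx <- idx[t >= window[1] & idx >= 1L & idx <= n_bins]
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  if (n_neurons(x) == 0L) counts <- matrix(integer(0), nrow = n_bins, ncol = 0L)
  if (n_bins == 1L) counts <- matrix(counts, nrow = 1L,
                                     dimnames = list(NULL, x$neuron_ids))
  population_trajectory(counts, bin_width,
                        bin_starts = window[1] + (seq_len(n_bins) - 1L) * bin_width,
                        neuron_ids = x$neuron_ids)
}

#' @rdname bin_population
#' @param counts T x N integer matrix of firing counts.
#' @param bin_starts Start time (s) of each bin.
#' @param neuron_ids Neuron identifiers (columns of `counts`).
#' @export
population_trajectory <- function(counts, bin_width, bin_starts = NULL,
                                  neuron_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("firing counts must be non-negative")
  if (is.null(bin_starts)) bin_starts <- (seq_len(nrow(counts)) - 1L) * bin_width
  if (is.null(neuron_ids)) neuron_ids <- colnames(counts)
  structure(list(counts = counts, bin_width = as.numeric(bin_width),
                 bin_starts = as.numeric(bin_starts),
                 neuron_ids = neuron_ids),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("population_trajectory: %d bins x %d neurons at %.0f ms\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_width))
  invisible(x)
}

#' Per-bin state trajectory across possibly discontiguous epochs
#'
#' Bins each epoch of the requested state separately (so bins never straddle
#' an epoch boundary) and concatenates the resulting trajectories. Used to
#' build per-state trajectories for windowed recurrence analysis.
#'
#' @inheritParams restrict_to_state
#' @param bin_width Bin width (s).
#' @return A `population_trajectory`; its `bin_starts` keep the original
#'   session clock, so time is discontinuous across epochs.
#' @export
state_trajectory <- function(x, hyp, state, bin_width = 0.05) {
  ep <- hyp[hyp$state == state, , drop = FALSE]
  if (nrow(ep) == 0L) stop("no epochs of state ", state)
  parts <- lapply(seq_len(nrow(ep)), function(i) {
    if (ep$end[i] - ep$start[i] < bin_width) return(NULL)
    bin_population(x, bin_width, window = c(ep$start[i], ep$end[i]))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L) stop("all ", state, " epochs shorter than one bin")
  population_trajectory(do.call(rbind, lapply(parts, `[[`, "counts")),
                        bin_width,
                        bin_starts = unlist(lapply(parts, `[[`, "bin_starts")),
                        neuron_ids = x$neuron_ids)
}
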