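#' Permutation entropy
#'
#' Shannon entropy (natural log) of the distribution of ordinal patterns of
#' `D` points taken `tau_embed` samples apart, over all sliding windows.
#' Ties are ranked by order of appearance, so integer-valued signals (spike
#' counts) are handled deterministically.
#'
#' @param x Numeric vector (or `field_signal`).
#' @param D Embedding order (pattern length), default 3.
#' @param tau_embed Embedding delay in samples, default 5.
#' @return Entropy in nats, in `[0, log(factorial(D))]`.
#' @export
permutation_entropy <- function(x, D = 3L, tau_embed = 5L) {
  if (inherits(x, "field_signal")) x <- x$samples
  n <- length(x)
  span <- (D - 1L) * tau_embed
  if (n < span + 2L) stop("series too short for the requested embedding")
  n_win <- n - span
  # pattern id: rank vector (ties by first occurrence) encoded in factorial base
  emb <- vapply(0:(D - 1L), function(j) x[(1L + j * tau_embed):(n_win + j * tau_embed)],
                numeric(n_win))
  if (n_win == 1L) emb <- matrix(emb, nrow = 1L)
  ids <- apply(emb, 1L, function(v) {
    paste(order(v), collapse = ".")  # order() breaks ties by position
  })
  p <- tabulate(factor(ids)) / n_win
  -sum(p * log(p))
}

#' Sample entropy
#'
#' `SE = -log(A/B)` where `B` counts vector pairs (length `m`) and `A`
#' pairs (length `m + 1`) whose Chebyshev distance is strictly below the
#' tolerance `r = r_frac * SD` of the analysed signal (identical templates
#' always match, so a constant series yields SE = 0); self-matches are
#' excluded. The signal is first decimated by `downsample` (every k-th
#' sample), mirroring a permutation-entropy delay of the same size.
#'
#' @param x Numeric vector (or `field_signal`).
#' @param m Template length, default 3.
#' @param r_frac Tolerance as a fraction of the (population) SD, default 0.1.
#' @param downsample Integer decimation factor, default 5.
#' @return Entropy in nats; `NA` (with a warning) when no matches exist at
#'   either length, where the statistic is undefined.
#' @export
sample_entropy <- function(x, m = 3L, r_frac = 0.1, downsample = 5L) {
  if (inherits(x, "field_signal")) x <- x$samples
  z <- x[seq(1L, length(x), by = as.integer(downsample))]
  n <- length(z)
  if (n < m + 2L) stop("series too short after downsampling")
  r <- r_frac * pop_sd(z)
  # both lengths use the same n - m templates (standard convention), so a
  # constant series gives A = B and SE = 0
  B <- count_cheb_pairs(z, m, r, n_templates = n - m)
  A <- count_cheb_pairs(z, m + 1L, r, n_templates = n - m)
  if (A == 0 || B == 0) {
    warning("no template matches; sample entropy undefined")
    return(NA_real_)
  }
  -log(A / B)
}

# number of unordered vector pairs (length m embeddings) with Chebyshev
# distance < r, self-matches excluded; chunked to bound memory
count_cheb_pairs <- function(z, m, r, n_templates = NULL) {
  n_vec <- length(z) - m + 1L
  if (!is.null(n_templates)) n_vec <- min(n_vec, n_templates)
  if (n_vec < 2L) return(0)
  emb <- vapply(0:(m - 1L), function(j) z[(1L + j):(n_vec + j)], numeric(n_vec))
  if (n_vec == 1L) emb <- matrix(emb, nrow = 1L)
  total <- 0
  chunk <- max(1L, floor(4e6 / n_vec))
  i0 <- 1L
  while (i0 <= n_vec - 1L) {
    i1 <- min(i0 + chunk - 1L, n_vec - 1L)
    rows <- i0:i1
    dmax <- matrix(0, length(rows), n_vec)
    for (j in seq_len(m))
      dmax <- pmax(dmax, abs(outer(emb[rows, j], emb[, j], "-")))
    # strict "< r" matching; identical templates always match so the r = 0
    # degenerate case (constant series) stays defined with SE = 0
    hit <- dmax < r | dmax == 0
    # count only pairs (i, k) with k > i to avoid double/self counting
    ut <- outer(rows, seq_len(n_vec), "<")
    total <- total + sum(hit & ut)
    i0 <- i1 + 1L
  }
  total
}

#' Lempel-Ziv (LZ-76) complexity
#'
#' Binarizes the signal at its mean (strictly greater than the mean maps to
#' 1, so a constant series becomes all zeros), parses the binary string
#' into phrases by the exhaustive LZ-76 scheme, and normalizes the phrase
#' count `c` as `c / (w / log2(w))` for string length `w`. Random binary
#' strings approach 1; constant or periodic strings stay near 0.
#'
#' @param x Numeric vector (or `field_signal`), length at least 2.
#' @return Normalized complexity (non-negative).
#' @export
lempel_ziv_76 <- function(x) {
  if (inherits(x, "field_signal")) x <- x$samples
  w <- length(x)
  if (w < 2L) stop("series too short")
  s <- as.integer(x > mean(x))
  lz76_phrases(s) / (w / log2(w))
}

# exhaustive LZ-76 parsing phrase count (Kaspar-Schuster algorithm)
lz76_phrases <- function(s) {
  n <- length(s)
  cnt <- 1L; l <- 1L; i <- 0L; k <- 1L; kmax <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cnt <- cnt + 1L; break }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == l) {
        cnt <- cnt + 1L
        l <- l + kmax
        if (l + 1L > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cnt
}

#' Complexity panel for a signal
#'
#' Convenience wrapper computing permutation entropy, sample entropy and
#' LZ-76 complexity with the package defaults.
#'
#' @param x Numeric vector or `field_signal`.
#' @param D,tau_embed,m,r_frac,downsample Passed to the individual measures.
#' @return Named list `pe`, `se`, `lz` plus the parameters used.
#' @export
complexity_panel <- function(x, D = 3L, tau_embed = 5L, m = 3L, r_frac = 0.1,
                             downsample = 5L) {
  list(pe = permutation_entropy(x, D, tau_embed),
       se = sample_entropy(x, m, r_frac, downsample),
       lz = lempel_ziv_76(x),
       params = list(D = D, tau_embed = tau_embed, m = m, r_frac = r_frac,
                     downsample = downsample))
}
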