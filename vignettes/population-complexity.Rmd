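---
title: "Recurrence and complexity of neural populations across sleep-wake states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence and complexity of neural populations across sleep-wake states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepdyn)
```

## The scientific question

During slow-wave sleep (SWS) the complexity of cortical field recordings
drops, while wakefulness and REM sleep look irregular and "complex". The
hypothesis this package operationalizes is that the drop is a population
phenomenon caused by DOWN states: synchronous silences of the whole
ensemble that force the population trajectory back to the same point of
phase space (the origin) over and over. `sleepdyn` provides the complete
analysis chain needed to test that idea on spike-time data — recurrence
quantification of population trajectories, DOWN/OFF-state detection,
synthetic field potentials with entropy measures, avalanche scaling, and a
critical branching simulator — plus a generator of ground-truth-labelled
synthetic sessions so that every stage can be validated without access to
the original recordings.

## Population trajectories and recurrence quantification

Spike trains of the N simultaneously recorded neurons are binned into
non-overlapping 50 ms count windows. The vector of counts
$\vec{x}(t_i) = (x_1(t_i), \dots, x_N(t_i))$ is one point of an
N-dimensional phase-space trajectory. The recurrence plot is

$$R(i,j) = 1 \iff \lVert \vec{x}(t_i) - \vec{x}(t_j) \rVert \le \varepsilon,$$

with Euclidean norm by default (Chebyshev available) and the comparison
inclusive, so $\varepsilon = 0$ still marks exact repeats of a firing
pattern. The tolerance is $\varepsilon = \sigma_P$, the population
standard deviation across time of the neuron-summed counts during
wakefulness of the same session (`wake_epsilon()`); for simulations the
baseline (non-silenced) run plays the role of wakefulness. The 50 ms bin
matches the minimum duration of a neocortical OFF period, and 10 s windows
(T = 200 bins) are scored separately so that state comparisons use a
distribution of windows per state.

Five standard measures summarize each window (`rqa_metrics()`):

* **RR** — density of recurrent points (identity included, per the
  $\frac{1}{T^2}\sum_{ij} R_{ij}$ definition);
* **DET** — fraction of recurrent points on diagonal lines of length
  $\ge l_{\min}$;
* **LAM** — fraction on vertical lines of length $\ge v_{\min}$;
* **TT** — mean vertical-line length (0 when no line qualifies, avoiding
  a 0/0);
* **DIV** — inverse of the longest diagonal excluding the identity line;
  a plot with only isolated points has $L_{\max} = 1$ and DIV $= 1$.

Conventions the definitions leave open were fixed as follows. The
identity line is excluded from DET's numerator and denominator (a Theiler
window of 1) — it carries no dynamical information — and a flag
(`include_loi_det`) restores it. Vertical structures crossing the identity
are genuine trapping and are kept in LAM/TT. $l_{\min} = v_{\min} = 2$,
the standard recurrence-analysis convention. The line-histogram
implementation is checked exactly, point for point, against a brute-force
enumeration oracle on random symmetric matrices.

## DOWN states

Two detection rules are provided, matching the two architectures the
method targets:

* **neocortex-OFF** (`detect_off_periods()`): maximal gaps of population
  silence lasting 50-1250 ms; ON periods are the segments between OFF
  periods with at least 10 spikes and 200-4000 ms duration.
* **hippocampus-fraction** (`detect_fraction_down()`): a bin is DOWN when
  strictly fewer than 10% of neurons fire in it, for structures that keep
  residual firing during DOWN states.

OFF intervals are rasterized onto the 50 ms bin grid by a majority rule (a
bin is DOWN when at least half of it is covered), which is symmetric and
quantizes interval bounds by at most one bin. The link between DOWN states
and recurrences is measured as the point-biserial correlation between the
binary DOWN series and the per-bin recurrence count
(`correlate_down_recurrence()`), and `exclude_down_bins()` builds the
time-compressed UP-only trajectory used to ask whether any state
difference survives once DOWN bins are gone. UP-only analysis concatenates
the remaining bins rather than re-windowing, so windows may span removed
time; the result carries a `time_compressed` flag. Both behaviours of the
correlation analysis (whole SWS vs UP-only) use the same Wake-derived
tolerance.

## Synthetic field potentials and complexity

Each excitatory neuron's binned spike counts are convolved with a causal
exponential kernel $e^{-t/\tau}$, $\tau = 24$ ms (a typical miniature-EPSP
decay for frontal pyramidal cells), truncated at $10\tau$ and normalized
to unit peak since amplitude units are arbitrary; the synthetic LFP is the
average over neurons, hence exactly linear in the spike input. The count
bin defaults to 8 ms, i.e. a 125 Hz sampling rate. The bin width and the
sampling rate cannot both equal their nominal descriptions ("80 ms bins"
vs "125 Hz") — 80 ms bins imply 12.5 Hz and could not support 1 Hz-resolution
spectra below 6 Hz — so the rate was taken as authoritative and the 80 ms
variant remains available through `bin_width`.

Spectra use Welch averaging over non-overlapping 1 s Hann segments (1 Hz
resolution), with one-sided density normalization verified by Parseval on
white noise. Coherence is the magnitude-squared estimator with the same
segmentation, averaged across segments before the ratio. The spectral
decay exponent $\alpha$ of $f^{-\alpha}$ comes from an ordinary
least-squares fit on the log-log spectrum.

Three complexity measures score the signals:

* **Permutation entropy**: Shannon entropy (nats) of ordinal patterns of
  $D = 3$ points at delay 5, over all sliding windows; ties are ranked by
  order of appearance, which makes integer-valued signals deterministic.
  A sliding-window scheme was chosen over non-overlapping blocks: it is
  the standard estimator the measure's definition refers to, and the
  block variant merely subsamples it.
* **Sample entropy**: $-\log(A/B)$ with Chebyshev distance, template
  length $m = 3$, tolerance $0.1 \times$ SD, strict `<` matching with
  identical templates always matching (so a constant series gives 0
  rather than an undefined ratio), self-matches excluded, the same
  $n - m$ templates at both lengths, and a decimation by 5 mirroring the
  permutation-entropy delay.
* **Lempel-Ziv (LZ-76)**: the signal is binarized at its mean (strictly
  greater maps to 1, so a constant series is all zeros), parsed by the
  exhaustive LZ-76 scheme, and the phrase count normalized as
  $c/(w/\log_2 w)$.

Log bases only rescale the entropies; natural log is used for the
entropies and base 2 for the binary LZ normalization.

## Avalanches and crackling noise

The merged population train is binned at its mean inter-spike interval
(computed per session and per state, since the rate differs across
states); an avalanche is a maximal run of non-empty bins delimited by
empty bins, runs touching the recording edges being discarded as
incomplete. Sizes and durations are fitted with a discrete power-law
maximum-likelihood estimator whose normalizer is the Hurwitz zeta
function; the lower cutoff is chosen by minimizing the Kolmogorov-Smirnov
distance (`xmin = "auto"`, the default, with a fixed-cutoff option since
the original choice is not recorded). Exponent uncertainty is a
nonparametric bootstrap (500 resamples by default). The crackling-noise
relation $(\tau_t - 1)/(\tau - 1) = 1/(\sigma \nu z)$ is tested by
comparing that exponent ratio against the ordinary least-squares slope of
log mean size versus log duration.

## The critical branching model

Fifty units on an Erdős–Rényi graph (attachment probability 0.03) evolve
in 1 ms steps through resting, firing and refractory states. A resting
unit fires when any neighbour that fired on the previous step succeeds in
an independent Bernoulli attempt with $P_{prop} = \sigma / \langle k
\rangle$ ($\langle k \rangle$ the realized mean degree), or when its
Poisson noise ($P = 1 - e^{-\lambda}$, $\lambda = 0.014$ per step) fires;
firing is followed by exactly one refractory step. Independent attempts
are the minimal reading of the pairwise propagation rule; links are
undirected ("each pair of units has a link"). SWS-like DOWN states are
imposed by periodically silencing the noise input of a fraction of units;
silencing never blocks propagation, only the noisy drive. The period
description ("250 ms at 4 Hz") is internally inconsistent — a 4 Hz cycle
is itself 250 ms — so the default schedule is 250 ms silence in a 500 ms
cycle (delta-band alternation), with both knobs configurable.

The implementation passes the phase-diagram checks that define the model:
with the noise off and a single seeded spike, sub-critical runs
($\sigma = 0.5$) die out in 100/100 repetitions while super-critical runs
($\sigma = 1.8$) mostly persist, and no unit ever fires on consecutive
steps. Seeded cascade ensembles at $\sigma = 1$ satisfy the crackling
relation within joint bootstrap intervals.

### A known, documented limitation

With the full stated parameterization ($\sigma = 1$ **and** the
$\lambda = 0.014$ noise), the ignited 50-unit network is self-sustaining
and saturates near 200 spikes/s per unit: critical branching with
constant immigration has no low-activity stationary state, and on this
small, sparse graph the ignited state persists even without noise. Binned
at 50 ms with $\varepsilon$ = 1 SD of the summed counts this yields
RR $\approx$ 0.98 and DET/LAM $\approx$ 1 — a frozen, fully recurrent
regime, not the sparse Wake-like regime with RR of a few percent that the
same analysis finds on irregular population data. Parameter sweeps over
$\sigma$, $\lambda$ and $\varepsilon$ show no point of this model family
that combines an RR of a few percent with moderate determinism and
laminarity, so the package reports what the stated dynamics produce
rather than curating parameters toward an expected output. The
phase-transition properties, the silencing mechanism, and the
avalanche/crackling behaviour of the model are all verified independently
of this regime question.

## The synthetic session generator

`gen_session()` emulates the statistical structure of the multi-electrode
recordings this analysis targets, with every label returned as ground
truth:

* 50 neurons with lognormal rates, median 2 Hz (`sdlog = 0.6`, a
  realistic skew for cortical populations: most neurons slow, a few
  fast);
* Wake and REM: independent Poisson trains at the per-neuron rates;
* SWS: a semi-Markov alternation of UP periods (uniform 200-4000 ms) and
  DOWN periods (uniform 50-1250 ms), matching the operational bounds of
  the detectors; uniform durations exactly respect those bounds, with a
  lognormal alternative left to future work;
* DOWN periods completely silent (neocortex-like) or carrying a fixed 10%
  subset of neurons at a low rate (hippocampus-like);
* UP periods fire at the same per-neuron rates as Wake. UP states are
  treated as fragments of wakefulness; rescaling UP rates to conserve the
  state-mean rate would make UP periods hotter than Wake and manufacture
  exactly the rate artifact it would be meant to prevent, so it is not
  done. Consequently the SWS mean rate is lower than Wake by the
  DOWN-time fraction, as in vivo.
* persistent activity: inside any firing segment, population gaps of
  45 ms or more are broken by a single injected spike from a random
  neuron (< 0.3% of spikes). Real ensembles in persistent-activity states
  essentially never fall population-silent at the OFF threshold — that is
  what makes the OFF-period definition usable — whereas independent
  Poisson trains do so by chance every few seconds.

What the generator does **not** emulate: bursting and refractory ISI
statistics, theta/ripple oscillations, and inter-neuron correlations
beyond the shared UP/DOWN modulation. Passing tests therefore demonstrate
that the analysis chain recovers planted structure of this kind; they do
not certify behaviour under oscillatory or strongly correlated regimes.
One visible consequence: the generator's count fluctuations are
Poisson-like, so recurrence saturates (RR $\to$ 1 for every state) once
the tolerance grows beyond about 3 SD, while real data keep a usable
dynamic range across the full 0-4 SD robustness sweep.

## Statistics

Windowed metrics are averaged per session and state; the omnibus test
across Wake/SWS/REM is a Friedman test on the session-by-state matrix
(sessions as blocks), followed by pairwise paired Wilcoxon signed-rank
tests with Benjamini-Hochberg correction at $\alpha = 0.05$, plus Cohen's
d (pooled-SD form) as effect size. The post-hoc named in the original
statistical recipe (Siegel) has no implementation in this environment and
its exact variant is not specified; the signed-rank test is the standard
paired nonparametric replacement and the package treats the choice as
interchangeable. Cohen's d, the point-biserial correlation and the
percentile bootstrap CI are implemented in-repo because their exact
conventions matter; Friedman, Wilcoxon and BH adjustment are library
calls. A paired cohort needs at least 6 sessions for an exact signed-rank
test to clear $p < 0.05$ after BH correction over three pairs — the
package's synthetic cohorts use 6.

## Problem sizes used by the test-suite and acceptance analyses

Synthetic sessions are 900 s (300 s per state) for acceptance-level
checks and 360 s for unit-level checks; the branching-model acceptance
analysis uses ten realizations of $10^6$ 1 ms steps; avalanche ensembles
use 2000-3000 seeded cascades; power-law recovery uses $10^5$ draws.
These sizes put every Monte-Carlo check comfortably beyond its assertion
tolerance while keeping a full run of the suite in the minutes range.
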