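---
title: "Temporal alignment and progression scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal alignment and progression scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempoalign)
```

This vignette is the package's own account of the science it implements:
the alignment model and its assumptions, the similarity and progression
statistics, every tunable parameter with its default and rationale, what
the simulator does and does not emulate, and the numerical and design
choices made where the method description left the design open.

## The problem

Two expression time courses for the same gene — a query and a reference —
may differ in length, sampling density and time window, and may be related
nonlinearly in time: one condition can be delayed, can progress at a
different pace, or can switch pace partway through. Point-by-point
correlation requires matched time grids and only captures linear
associations. The approach here is alignment-based: warp the two time axes
onto each other, decide whether the warped patterns genuinely agree, and
then read the progression difference off the warp itself.

## Alignment model

Trajectories are compared after unit scaling (see *Preprocessing*), so
alignment operates on shape, not amplitude. Dynamic time warping finds the
monotone, contiguous path through the (query index, reference index) grid
minimising accumulated local cost. Fixed choices, all guarded by an
exhaustive-enumeration oracle in the test suite:

* **Local cost**: absolute difference of the scaled values.
* **Step pattern**: symmetric2 — diagonal steps accumulate twice the local
  cost, horizontal/vertical steps once. This is the common default for
  expression-series warping and keeps the path measure symmetric in the
  two series.
* **Tie-break**: when several paths are cost-optimal the backtrace prefers
  the diagonal, then the step advancing the query. Truncation outcomes
  depend on the specific path, so the tie-break is part of the method, not
  an implementation detail.

DTW's endpoint constraint forces the first and last indices of both series
to align. When the true overlap is partial — a delayed query, or a faster
series that exhausts the shared window early — the out-of-overlap points
duplicate onto the partner's first or last index. Truncation corrects
this:

* **Head rule**: if the first $m$ indices of one series all map to the
  other's first index, drop the first $m-1$ of those pairs, keeping the
  last (the genuine entry point into the overlap).
* **Tail rule**: at the first path step touching the last index of either
  series, drop everything after it.

Both rules only ever remove a prefix or suffix, so the retained index
ranges are contiguous. If fewer than three aligned pairs survive, the pair
is reported non-STP with reason `insufficient_overlap` rather than
crashing: downstream statistics are meaningless on two points.

## Similarity metrics and the STP call

Four metrics are computed on the truncated alignment; a pair must pass all
of them jointly:

| metric | definition | threshold (default) |
|---|---|---|
| pct(query) | retained query time span / total query span | max of the two > 0.80 |
| pct(reference) | likewise for the reference | min of the two ≥ 0.50 |
| ρ | Spearman correlation of aligned value pairs | > 0.90 |
| p | shuffle-null tail probability of ρ | < 0.05 |

The percentages are ratios of *time intervals*, not index counts, so they
remain meaningful under non-uniform sampling. The asymmetric percentage
thresholds encode that when one pattern resembles only part of the other,
the longer matched pattern should retain most (80%) of its data and the
shorter at least half.

The p-value permutes the values of both series independently (times
fixed), re-runs the entire align–truncate–correlate pipeline per shuffle
(100 by default), fits a Gaussian to the null correlations and reports the
upper tail $P(N(\mu,\sigma^2) \ge \rho_{obs})$. The upper tail is the only
direction consistent with the test's premise — a genuinely similar pair
should correlate *higher* than its shuffled versions. Shuffles whose
truncated overlap degenerates are dropped from the fit; if the null is
degenerate ($\sigma = 0$) the p-value falls back to 0/0.5/1 by the sign of
$\rho_{obs}-\mu$ with a warning.

**Calibration and its limits.** On exchangeable null data (white-noise
series) the permutation test is calibrated; the test suite verifies the
rejection rate at 0.05 stays within its binomial interval. On
*autocorrelated* null data — two independent but individually smooth
trajectories — the shuffle null is anticonservative, because shuffling
destroys smoothness and DTW aligns two smooth curves far better than two
rough ones. The test suite measures this directly: independent smoothed
draws are rejected at far above nominal rate by the p-value alone. This is
a structural property of permutation nulls under autocorrelation, shared
by the method as published, and it is why the p-value is only one of four
joint criteria: in the same experiment the percentage-of-alignment and
ρ > 0.9 thresholds reject most independent smooth pairs that the p-value
alone would pass. Interpret the p-value as a guard against small-sample
chance alignments, not as a calibrated significance statement about smooth
data.

## Progression scoring

For an STP pair, each retained query time is mapped to the mean of its
aligned reference times, giving the empirical warp $w(t)$. If the two
series progressed identically, $w$ is the diagonal; a delay shifts it
vertically; a pace difference tilts it.

**Piecewise fit.** A segmented linear model is fitted to $(t, w(t))$:
for every number of breakpoints $K = 0..N$ (default $N = 10$) the
least-squares optimal placement over the observed query times is found by
exact dynamic programming (each segment spans at least two points;
segments are independent regressions — continuity at breakpoints is *not*
enforced, matching the merge step's per-segment refit semantics). The
model minimising

$$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + p \ln n, \qquad p = 2(K+1) + K$$

is selected. On noiseless input the RSS of a correct segmentation is
numerically zero and $\ln(\mathrm{RSS}/n)$ diverges, so the RSS entering
the BIC is floored at $10^{-10}$; all exact models then tie on the
likelihood term and the penalty selects the simplest, while on any
realistically noisy data the floor is inert. Adjacent segments whose
slopes differ by less than `delta_slope` (default 0.1, the resolution
below which two pace estimates are not considered distinct) are merged
smallest-difference-first, refitting a single regression on the combined
points, until no pair qualifies.

**PAS.** The Progression Advance Score is the signed area between the
fitted warp and the diagonal, normalised by the aligned query span.
Sign convention, declared in every report: **PAS > 0 means the query is
temporally advanced** (a query time maps to a later reference time); a
query delayed by a pure shift $\Delta$ scores $-\Delta$. Per-segment
slopes read as fold-speed of the query relative to the reference.

**c-PAS and adjusted PAS.** The condition-level warp takes, per query
time, the *median* aligned reference time across all STP genes — but only
at query times retained by at least 50% of them, so that heavily truncated
genes do not distort the edges; the pointwise median of monotone warps can
dip by floating-point ties, so it is passed through a running maximum
before fitting. c-PAS is the PAS of that warp, and adjusted PAS = PAS −
c-PAS isolates gene-specific progression from the conditions' overall pace
difference. Over a simulated cohort whose per-gene shifts are a common
delay plus zero-median noise, the adjusted PAS distribution centres at
zero within one sampling interval (verified in the tests).

## Preprocessing

* **Normalisation**: median-of-ratios size factors estimated over genes
  positive in every sample (cross-checked in the tests against DESeq2's
  estimator). Note the estimator is scale-equivariant only up to a global
  constant: multiplying one sample by $c$ rescales the whole normalised
  matrix by $c^{1/m}$. Trajectory *shapes*, which are all that alignment
  sees after unit scaling, are unaffected.
* **Replicates** are averaged after normalisation.
* **Filtering**: genes must change at least `fold_threshold`-fold
  (default 2) over the time course. The fold change is computed as
  $(\max + 1)/(\min + 1)$ so that zero minima are well-defined, mirroring
  the pseudo-count of the subsequent $\log_{10}(x+1)$ transform.
* **Unit scaling**: per gene, $(x - x_{min})/(x_{max} - x_{min})$ with
  the min/max taken *jointly* over query and reference by default, so a
  gene that never reaches its cross-condition maximum in one condition is
  visibly lower there. Per-series scaling is available
  (`joint_scaling = FALSE`) for cross-platform inputs whose absolute
  units are incomparable; a per-matrix scalar divisor handles gross unit
  mismatches before normalisation.
* **Pseudo-time**: series with large sampling gaps bias both the warping
  (spurious duplications across the gap) and the breakpoint placement;
  `to_pseudotime()` replaces times by their rank order $0,1,\dots,n-1$,
  after which the method detects time-*order* similarity. All time-unit
  quantities (percentages, PAS) are then in order units.

## The simulator

`pattern_spec()`/`generate_pair()` produce pairs with analytically known
warps: time shifts ($w(t) = t-\Delta$), $k$-fold speed changes
($w(t) = t_0 + k(t-t_0)$), mixed piecewise regimes, and dissimilar pairs,
with additive noise $K \cdot N(0,1)$ applied independently to both series.
The default base curve is a logistic sigmoid spanning the window (tenth-of-
window scale), with Gompertz and linear-ramp templates and arbitrary
user functions pluggable; the defaults place one clean rise inside the
observation window, the regime the truncation rules were designed around.

Two constructions deserve comment:

* **Mixed regimes**: for a query 2-fold faster over the first 50 of 100
  days, the reference must run to day 150 for both regimes to be
  observable, so the reference window is the warped image of the query
  window. Sampling both on the same window would tail-truncate the second
  regime entirely. With daily sampling, a 2-fold regime matches each query
  day to two reference days; together with head truncation this can leave
  a one-or-two-point boundary sliver as an extra fitted segment beside the
  two regime segments. The regime slopes themselves are recovered exactly.
* **Dissimilar pairs** are *independent* smoothed-Gaussian draws (kernel
  bandwidth 10% of the window — a handful of turning points per time
  course, roughly what developmental trajectories show). Independence is
  the right construction for a null, but it does not guarantee visual
  dissimilarity: two independent draws are occasionally both monotone and
  genuinely warpable onto each other, and the classifier rightly calls
  those similar. Ground-truth labels from this generator are therefore
  slightly noisy by design.

What the simulator does **not** emulate: count-level sampling noise
(negative binomial reads), gene–gene correlation, platform batch effects,
or missing time points. Passing the simulation suite shows the algorithmic
machinery recovers known warps under Gaussian noise; it does not certify
performance on any particular real dataset.

## Problem sizes and determinism

The test and acceptance workloads use windows of 0–100 days at 0.25–1
samples/day, 100-shuffle nulls, 50 repetitions per power-sweep cell and
200 pairs for the calibration and oracle suites — sizes chosen so every
behaviour of interest (truncation percentages, slope recovery, power
ordering in noise and density) is resolved while the whole suite stays
interactive. All randomness flows from one master seed through named
substreams (`stream_seed(seed, key)`), so per-gene results are independent
of processing order and bit-for-bit reproducible.

## Known limitations

* The shuffle p-value is anticonservative on autocorrelated null data
  (see above); joint thresholds mitigate but do not remove this.
* No multiple-testing correction across genes: the STP call thresholds
  the raw p-value at 0.05, as the four-way joint requirement, not the
  p-value alone, carries the specificity.
* Segmented fits do not enforce continuity at breakpoints, and breakpoint
  uncertainty is not quantified.
* Only two-series comparisons; multi-condition alignment and open-end DTW
  variants are out of scope.
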