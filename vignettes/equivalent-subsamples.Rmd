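---
title: "Splitting samples into equivalent subsamples: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting samples into equivalent subsamples: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(equisplit)
```

## Why split a sample at all

Exploratory and confirmatory factor analysis on the same data capitalizes on
chance: whatever idiosyncratic structure the EFA picked up, the CFA will
happily "confirm". The remedy is cross-validation on two halves of one
sample — but only if the halves are *equivalent*, i.e. both contain all the
sources of common variance present in the full sample. This package provides
splitters designed to produce such halves, and an index to check that they
did.

## The equivalence index

Factor analysis operates on a correlation matrix, and the
Kaiser–Meyer–Olkin (KMO) statistic summarizes how much common variance that
matrix carries: the ratio of summed squared correlations to summed squared
correlations plus summed squared anti-image partial correlations. `kmo()`
computes the overall measure from the inverse correlation matrix
($p_{jk} = -q_{jk}/\sqrt{q_{jj}q_{kk}}$ with $Q = R^{-1}$), the standard
Kaiser–Rice construction; per-variable MSA values, Bartlett's test and
polychoric variants are deliberately out of scope.

Two subsamples with the same common variance have (near-)equal KMOs, so the
**Communality Ratio**
$S = \min(\mathrm{KMO}_1, \mathrm{KMO}_2) / \max(\mathrm{KMO}_1,
\mathrm{KMO}_2)$
is 1 for equivalent halves and decays toward 0 as one half degenerates to
error variance. `assess_split()` packages the whole check: per-subsample
Pearson correlations, per-subsample KMO, and S. S is displayed to 4 decimals
but computed and stored at full precision.

A closed form worth knowing: with only $m = 2$ variables the partial
correlation equals the marginal one, so KMO is exactly $1/2$ for any
$r \neq 0$ — one of the test suite's anchors, along with an independent
oracle that obtains every partial correlation by regressing each pair on all
remaining variables and correlating residuals.

## The Solomon splitter

The method reduces each participant to a single position value and then
deals the sorted participants out alternately:

1. **Dimensionality** `q`: the count of correlation-matrix eigenvalues
   above 1 (Kaiser's rule), clamped to $[2, m-1]$. Kaiser's rule
   overestimates the number of interpretable factors, which is the point: it
   is a conservative *bound* that keeps every contributor to the common
   variance while discarding the bulk of the unique variance. The floor of 2
   prevents the ordering from collapsing onto a single axis; users with
   prior knowledge can pass `q` explicitly, and the advisable range is never
   above Kaiser's count.
2. **Projection**: items are standardized, and scores are raw projections
   onto the unit eigenvectors, $c_{ij} = z_i \cdot v_j$, so component $j$
   has variance $\lambda_j$. Whether such scores should instead be
   standardized to unit variance is genuinely open (the magnitudes of the
   published worked example are compatible with raw projections); raw
   projections are the literal reading of "projection on the component" and
   are what this package uses. Note the choice matters only through the
   ordering of the composite.
3. **Composite**: $d_i = \sum_{j=1}^{q} w_j c_{ij}$ with $w_j = \lambda_j/m$
   the proportion of total variance. Components that explain more variance
   contribute proportionally more to a participant's position.
4. **Assignment**: sort by $d_i$ descending — the worked example lists the
   largest composite first — with ties broken by original row order, then
   assign positions alternately; the odd leftover goes to subsample 1,
   matching the worked example's treatment of the 7th participant.

Consecutive participants in the ordering are maximally similar, so
alternation sends near-duplicates to opposite halves and each half spans the
full cloud. The procedure involves no random numbers: `solomon_split()` is
deterministic and permutation-invariant whenever the $d_i$ are distinct
(asserted as a property test).

**More than two subsamples.** For odd `k`, consecutive k-tuples of the
ordering are dealt across the k subsamples in sorted-position order (the
exact within-tuple order is unspecified in the original description; sorted
position is the natural deterministic choice). For even `k > 2` the sample
is halved and each half halved again, recursively. **Stratified splitting**
(`stratified_split()`) runs any splitter inside each level of a covariate
and pools stratum-level subsample 1's into global subsample 1, preserving
the covariate's proportions in both halves.

## The Duplex comparator

Duplex is the representative-subset selector from the
calibration/regression tradition: the farthest pair (Euclidean distance over
the raw item responses — a `scale` flag z-scores them first) seeds
subsample 1, the farthest remaining pair seeds subsample 2, and the
subsamples then alternate, each receiving the unassigned row whose minimum
distance to the subsample's current members is largest. Discrete Likert data
produce frequent exact distance ties; all ties resolve deterministically to
the lowest row index with a warning, so the implementation cannot fail to
converge — degenerate inputs (even all-identical rows) complete. An
exhaustive-loop oracle replays the same selection rules independently on
every instance with $n \le 10$ in the tests.

The implementation holds the full $n \times n$ distance matrix
(about 8 MB at $n = 1000$, growing quadratically) and updates per-point
minimum distances incrementally, so each greedy step is $O(n)$.

## Numerical choices

- **Eigenvector signs** are indeterminate; each eigenvector is flipped so
  its largest-magnitude loading is positive (ties to the lowest variable
  index). This fixes the composite's sign and hence the ordering across
  linear-algebra backends.
- **Near-singular correlation matrices** (subsample size close to the item
  count) get a ridge of $10^{-10}\,\mathrm{tr}(R)$ before inversion, with a
  warning. Because a correlation matrix's largest eigenvalue is at most $m$,
  the post-ridge condition number is bounded by about $10^{10}$, so the
  ridge always suffices for genuine correlation inputs; the hard error at
  condition number $10^{12}$ guards non-correlation input only.
- **PSD repair** of population correlation matrices built as
  $\Lambda\Lambda^\top$ with forced unit diagonal: negative eigenvalues are
  clipped to $10^{-10}$, the matrix reconstructed and rescaled to unit
  diagonal. With the loading ranges used here the repair perturbs entries by
  far less than 0.01 (asserted in tests) and rarely triggers at all.
- **Missing data** are rejected outright rather than imputed; zero-variance
  items are errors naming the offending column.

## What the generators emulate

`make_loadings_study1()` reproduces the sample-size-sweep population: 5
orthogonal factors, 20 variables each, salient loadings uniform on
$[.40, .45]$, non-salient on $[-.10, .10]$ — a low-communality,
many-variable regime where splitting is hardest. A fresh loading matrix is
drawn per replication (regeneration, rather than reuse, is the default
answer to an ambiguity in the original design). `sample_continuous()` draws
multivariate-normal samples with the implied population correlation via
`MASS::mvrnorm` (symmetric eigendecomposition factorization), seeded and
bit-reproducible.

`make_loadings_study2()` covers the factorial design: communality `large`
(salient $U[.55, .88]$) vs `wide` ($U[.20, .88]$), 1–3 factors, 10/20/30
variables per factor, $N \in \{100, ..., 1600\}$, and two response styles.
Non-salient loadings are set to zero (only the salient ranges are specified
in the source design; zero is the clean simple-structure reading, recorded
as an open choice). Each condition simulates a finite population of 10,000
continuous response vectors, categorizes them to 5 points by comparing
against standard-normal quantiles of the cumulative proportions
(`normal`: .05/.26/.74/.95; `extreme`: .05/.10/.15/.25 — the values are
plainly probabilities, not z-cuts), and draws samples *without replacement*,
the natural reading of drawing from a fixed population. The design is not
fully crossed: cells with $N = 100$ and 60 or 90 variables are rejected at
construction (subsamples of 50 with that many items are unrealistic),
leaving 168 valid cells.

What the generators do **not** emulate: oblique factors, skewed latent
distributions, missing data, item-specific thresholds, and real-data
features such as careless responders. Passing simulation benchmarks
therefore shows the splitters behave as designed under clean orthogonal
factor models, not that S will be as high on messy empirical data.

## Experiment drivers and problem sizes

`run_study1()` sweeps sample sizes with a configurable replication count
(default 30; the original design used 100 — available via the
`replications` argument) and `run_study2()` runs the factorial design
(default 50 replications per cell vs the original 1,000). These defaults are
the package's desk-scale choice: they keep a full N = 500/1000 sweep with
both splitters around half a minute while leaving the Monte-Carlo standard
error of a cell mean a few thousandths, small enough for the 3-standard-error
comparisons used in the acceptance tests. Every stochastic step's seed
derives from one master seed, so entire sweeps are bit-reproducible, and
per-replication logs are retained (`tidy()`) so any summary cell can be
re-derived — an aggregation identity the tests assert. Failures of a
splitter on a particular sample are counted, never fatal; with the
deterministic tie-breaking above, Duplex cannot fail here, so its failure
count is expected to be 0. Timing is not asserted anywhere: it is
hardware-bound and out of scope.

## Known limitations

- KMO on 5-point categorized data uses Pearson correlations; ordinal
  (polychoric) adequacy assessment is a non-goal, and S values on coarse
  scales inherit Pearson's attenuation.
- Kaiser's rule is a bound, not a factor-count recommendation; the retained
  `q` says nothing about how many factors to extract in the follow-up EFA.
- The Duplex implementation targets $n$ in the thousands; memory grows as
  $n^2$ and it is markedly slower than Solomon, which is linear in $n$
  after one $m \times m$ eigendecomposition.
- With heavily discrete data, many tied composites push the Solomon
  ordering toward the row-order tie-break; the split remains valid but the
  "most similar neighbours" rationale weakens.
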