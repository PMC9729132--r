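# equisplit

Splitting a participants-by-items sample into *equivalent* subsamples for
factor-analysis cross-validation.

## The problem

A common workflow in scale development is to split one sample in two: run an
exploratory factor analysis (EFA) on the first half and confirm the model
(CFA) on the second. That only makes sense if the two halves carry the same
common variance — a random split can, by bad luck, put most of the
factor-driven respondents in one half. `equisplit` implements a fast,
deterministic splitting method built on principal components (the *Solomon*
method), alongside its main comparators, and a quality index that measures
how equivalent the resulting halves actually are.

## The method

**Equivalence index.** The Kaiser–Meyer–Olkin statistic of a correlation
matrix `R` with inverse `Q`,

    KMO = Σ_{j≠k} r_jk² / ( Σ_{j≠k} r_jk² + Σ_{j≠k} p_jk² ),
    p_jk = −q_jk / √(q_jj q_kk),

is near 1 when correlations dominate partial correlations, i.e. when the
matrix is rich in common variance. Two subsamples are equivalent when their
KMO values agree, which the **Communality Ratio**

    S = min(KMO₁, KMO₂) / max(KMO₁, KMO₂)

scores in (0, 1], with S = 1 for perfectly equivalent halves.

**Solomon splitting.** Standardize the items, eigendecompose the Pearson
correlation matrix, and retain `Q` components (Kaiser's
eigenvalue-greater-than-one count, clamped to `[2, m−1]`). Each participant
gets the single ordering value

    dᵢ = Σ_{j=1}^{Q} w_j c_ij,      w_j = λ_j / m,

the variance-weighted sum of their component projections. Sorting by `dᵢ`
and dealing participants out alternately (odd positions → subsample 1, even
→ subsample 2) places the most similar participants in opposite halves, so
both halves span the whole cloud. No randomness anywhere: the split is
reproducible by construction.

**Comparators.** `duplex_split()` implements the Duplex max–min Euclidean
distance selection from the calibration/regression literature (farthest pair
seeds subsample 1, next farthest pair subsample 2, then alternating max–min
additions, ties broken by lowest row index), and `random_split()` the seeded
random baseline. `stratified_split()` applies any of the three within the
levels of a covariate (e.g. gender) and merges the halves.

A Monte-Carlo toolkit (`make_loadings_study1()`, `make_loadings_study2()`,
`sample_continuous()`, `categorize()`, `run_study1()`, `run_study2()`)
generates orthogonal-factor populations, continuous and 5-point categorized
samples, and benchmarks the splitters by mean S across designs.

## Worked example

Seven participants answered a 5-item questionnaire. Two components are
retained (41.1% and 17.5% of variance); from their printed projections the
weighted composites and the alternating assignment are:

```r
library(equisplit)
proj <- rbind(c(2.617, 1.140), c(2.065, 1.094), c(2.540, -1.002),
              c(2.062, -1.324), c(-0.429, 0.759), c(-0.937, 0.714),
              c(-1.630, -0.875))
d <- composite(proj, c(0.411, 0.175))
round(d, 3)
#> [1]  1.275  1.040  0.869  0.616 -0.043 -0.260 -0.823
solomon_assign(d)
#> [1] 1 2 1 2 1 2 1
```

Sorted by `d`, participants 1, 3, 5, 7 (Teresa, Gabriel, Laura, Carlota) go
to subsample 1 and participants 2, 4, 6 (Daniel, David, Maria) to
subsample 2 — the odd leftover lands in subsample 1.

On a realistic sample, the full pipeline and its quality report:

```r
set.seed(2026)
x <- as.data.frame(matrix(rnorm(400 * 12), 400, 12) + rnorm(400))
sp <- solomon_split(x)
glance(sp)
#> # A tibble: 1 × 5
#>   method      k     n size_min size_max
#>   <chr>   <int> <int>    <int>    <int>
#> 1 solomon     2   400      200      200
assess_split(x, sp)
#> Split adequacy report
#>   subsample sizes : 200 / 200 (m = 12 items)
#>   KMO total       : 0.9622
#>   KMO subsamples  : 0.9544 / 0.9516
#>   Communality S   : 0.9971
```

S = 0.9971 says the halves are near-perfectly equivalent in common
variance; both subsample KMOs sit slightly below the whole-sample KMO, as
expected when the most informative respondents are shared out between the
halves. `tidy()`/`glance()` give tibble views of every result object, and
`autoplot()` draws the composite ordering or a simulation summary.

A thin command-line interface over the same functions ships in
`inst/cli/equisplit.R` (subcommands `split`, `adequacy`, `generate`,
`simulate`).

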