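---
title: "The permutational DBI potential: model, calibration and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The permutational DBI potential: model, calibration and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbiperm)
```

## The index and the two classical summaries

The Dragonfly Biotic Index (DBI) assigns every odonate species a score from
0 (widespread, unthreatened generalist) to 9 (restricted, endangered,
highly sensitive specialist), the sum of three subindices — geographical
distribution, IUCN threat status and sensitivity to disturbance — each
scored 0–3. A site's conservation value is classically summarized either as

* **DBI_sum** — the sum of the scores of all species present, or
* **DBI_mean** — DBI_sum divided by species richness.

The two disagree in characteristic ways. DBI_sum grows with richness, so a
large community of mediocre species can outrank a small community of
top-scoring specialists; DBI_mean is dragged down by harmless generalists,
so a high-quality community supplemented with a few common species can fall
below a poorer but "purer" one. Neither behavior is what a conservation
prioritization exercise wants.

## The permutational DBI potential

The potential asks a different question: *among all communities of the same
richness that could plausibly be assembled from the regional pool, what
fraction does this community beat?* Concretely, for a community of richness
$k$ on a pool of $n$ scored species:

1. assemble `n_perm` (default 10,000) random communities of exactly $k$
   distinct species, drawing sequentially **without replacement** with the
   probability of each remaining species proportional to its weight
   $x^{-\mathrm{DBI}}$;
2. count the draws whose DBI_sum is **strictly below** the observed
   community's DBI_sum;
3. the potential is that count divided by `n_perm`.

The statistic lies in $[0, 1]$ and reads as a percentile: 1 means no random
same-richness community does as well; 0 is attained exactly by the
community realizing the minimum possible sum for its richness (no draw can
be strictly lower — this is a hard identity, not a sampling statement, and
the test suite asserts it across seeds). Because the comparison is within a
richness class, the potential inherits DBI_mean's robustness to sampling
effort while remaining, like DBI_sum, insensitive to padding a top-quality
community with low-scoring species.

Draws that *tie* the observed sum are counted separately and excluded from
the numerator: "lower" is read strictly. A mid-p variant
(`mid_p = TRUE`, crediting half of the ties) is available for users who
prefer the less conservative percentile convention, but it is not the
default and none of the reported results use it.

### The weight function and its calibration

The geometric weight $x^{-\mathrm{DBI}}$ encodes the assumption that each
unit increase of the DBI roughly halves a species' probability of
occurrence, so that two communities with equal richness and equal DBI_sum
have (approximately) equal potential regardless of how the sum is composed.
The base $x$ is an empirical quantity. `calibrate_weight_base()` estimates
it from quadrat occupancy: each species' occupancy rate is its
occupied-quadrat count relative to the most common species; rates are
averaged within distribution-subindex (DBID) classes 0, 1 and 2; the two
successive class-mean ratios measure the per-step frequency drop; and the
recommended $x$ is the reciprocal of their geometric mean, rounded to the
nearest integer (the unrounded value is always reported alongside).

```{r calibration}
calibrate_weight_base(c(0.80, 0.38, 0.18))
```

Class 3 is excluded from the calibration: DBID = 3 species tend to occur at
range edges and the subindex is strongly confounded with the threat and
sensitivity subindices there. The rounding-to-integer step is this
package's choice — the halving reading of ratios near 0.47 — and the
geometric-mean-then-round rule is one defensible formalization of an
informal observation; users who prefer the unrounded base can pass it to
`weight_scheme()` directly. `base_x = 1` gives uniform weights, i.e. simple
random subsets, which the test suite uses as a degenerate cross-check.

### Sampling scheme

"Weighted sampling without replacement" is ambiguous across fields. This
package uses *successive* sampling: each draw picks one remaining species
with probability proportional to its weight among those still available,
i.e. the scheme implemented by R's own unequal-probability `sample()`,
which is what existing DBI tooling in R relies on. Conditional Poisson
sampling and other fixed-inclusion-probability designs would give different
subset probabilities. The choice is pinned by an exact test oracle
(`exact_potential_oracle()`) that enumerates every ordered draw with its
product of conditional probabilities on tiny instances (pool ≤ 10,
richness ≤ 4) and is itself checked against an independent enumeration and
against hypergeometric subset counts in the uniform-weight case. Weights
are renormalized implicitly after each draw (the successive scheme); a
draw-once-normalize-once reading would be a different scheme and is not
offered.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `base_x` | 2 | weight base; halving of occurrence probability per DBI unit |
| `n_perm` | 10,000 | Monte-Carlo permutations per potential |
| `reps`   | 100   | repetitions per site in the stability diagnostic |
| `alpha`  | 0.05  | significance level for the discrimination flag |
| `decay`  | 2     | frequency decay of the synthetic pool across DBI values |

At `n_perm` = 10,000 the Monte-Carlo standard error of a potential $p$ is
$\sqrt{p(1-p)/10^4} \le 0.005$, which supports the customary three-decimal
display. Potentials are stored at full precision; two-decimal DBI_mean and
three-decimal potential rounding happens only in printed/written output and
never feeds back into ranks.

## The synthetic pool

`synthetic_pool()` emulates a Central-European-like regional checklist:
68 scored species by default, every total score 0–9 represented, and the
number of species per score decaying geometrically (`decay^-value`,
default 2) so that widespread generalists dominate and top-scoring
specialists are single species. Counts per score are allocated by
deterministic largest-remainder rounding of the geometric quotas on top of
one guaranteed species per score; the seed only randomizes the split of
each total into the three subindices. With 68 species the per-score counts
are 30, 16, 8, 5, 3, 2, 1, 1, 1, 1.

What it does *not* emulate: real checklists have phylogenetic and habitat
structure, correlated subindices, and score distributions that deviate from
a clean geometric law; vagrants and taxonomic synonyms complicate name
resolution. Tests passing on the synthetic pool therefore validate the
*machinery* (assembly, counting, ranking, bookkeeping) and the exact
boundary identities, not the published values that depend on the
composition of a real regional checklist — those require the user to load
the actual checklist CSV.

## Benchmark scenarios

`default_scenarios()` reproduces the thirteen extreme compositions used to
contrast the three summaries: giant (38 species), large (20; 21 for the
'A'+1'B' case, forced by its mean of 167/21), medium (10) and small (2)
communities of species categories A (DBI 8–9), B (4–5), C (2–3) and
D (0–1). `build_scenario()` fills each category greedily from the band
extreme inward — A/B/C from the top of the band down, D from the bottom up —
and, when a band is *depleted*, substitutes unused species with the nearest
scores beyond the crossed boundary (next lower for A/B/C, and only once
everything below is exhausted the values above the band; next higher for D,
which is what lets a giant community of pure generalists sum above its
richness on a real checklist). Ties within a score follow checklist order,
so scenario construction is fully deterministic given the pool, and every
substitution is recorded in the result. Ranks on the three metrics are
dense descending ranks (1 = most valuable, ties share the better rank),
computed on full-precision values.

On the synthetic pool most band-filling involves substitutions (the pool
holds only one species each at scores 6–9 by design), so the scenario sums
and means are pool-specific; the structural facts — the pure-generalist
giant community at potential exactly 0.000, the 'A'-dominated rows
saturating at 1.000, the rank reversals between DBI_sum and DBI_mean — are
reproduced and asserted in the tests.

## Stability diagnostic

Because the potential is a Monte-Carlo statistic, `repeat_potential()`
recomputes it `reps` times per site (fresh permutations each time, child
seeds derived deterministically from one master seed) and
`stability_report()` compares sites pairwise with two-sample
Kolmogorov–Smirnov tests, Bonferroni-adjusted over the $n(n-1)/2$
comparisons. Asymptotic (not exact) p-values are used: at 100 repetitions
per side this is standard, and potential values are heavily tied, which
rules out the exact small-sample distribution anyway.

Two design points deserve note. First, a pair of sites whose potential
distributions are both degenerate at the same point — typically two
saturated sites at 1.000 in every repetition — is flagged *indistinct*
directly, without leaning on the KS p-value, which is uninformative for
point masses. Second, no single significance threshold is hard-coded as
"the" discrimination criterion: the report carries raw and adjusted
p-values and the flag uses a configurable `alpha` (default 0.05), so users
can apply their own standard.

## Numerical and degenerate-input choices

* Richness equal to the pool size is permitted with a warning: every draw
  is then the full pool and the potential is 0 by construction.
* Abundances are coerced to presence (`abundance > 0`); non-numeric
  abundance cells are an error, never silent absence, because silent
  absence corrupts richness.
* Name matching trims and collapses whitespace and folds case; the
  checklist spelling is preserved in all output. Unmatched sample names
  are errors in strict mode, dropped-and-reported otherwise.
* Species without a defined DBI score are excluded from a loaded checklist
  with a message — never imputed.
* Vagrant filtering is deliberately left to the user: no operational
  vagrancy rule exists, so the package computes on exactly the members it
  is given.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run the full
10,000-permutation setting for the headline quantities (boundary
potentials, oracle agreement on 20 tiny random instances) and scaled-down
permutation counts (150–500) for the property checks that only exercise
bookkeeping, determinism and ranking, where the Monte-Carlo resolution is
irrelevant. Stability checks in the tests use 12–30 repetitions; the
default of 100 repetitions per site remains the recommendation for real
assessments.

## Known limitations

* The exact oracle is exponential and intentionally guarded to pool ≤ 10,
  richness ≤ 4; there is no closed form for large pools.
* The integer rounding of the calibrated base discards information; the
  unrounded value is reported so users can judge the rounding's effect.
* The potential compares communities *within* a richness class through a
  stochastic reference distribution; two sites can be individually
  saturated at 1.000 and therefore indistinguishable by the potential even
  though their DBI_sum and DBI_mean differ — the stability report makes
  such pairs visible rather than hiding them.
* No regional checklist is bundled; analyses of real data require the
  user's own scored checklist.
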