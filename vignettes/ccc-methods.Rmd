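---
title: "The Clustermatch Correlation Coefficient: model, implementation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Clustermatch Correlation Coefficient: model, implementation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccr)
```

## The model

The Clustermatch Correlation Coefficient (CCC) measures association between
two features by asking how well a coarse grouping of the samples induced by
one feature predicts a grouping induced by the other. Concretely:

1. **Partitioning.** A numeric feature is partitioned by empirical
   quantiles into $k$ near-equal clusters, for every $k$ in a configured
   range. The assignment is `label = min(floor(q * k), k - 1)` with
   $q = (\text{midrank} - 0.5)/n$, so tied values always share a cluster
   and the partition depends only on ranks. A categorical feature
   contributes exactly one partition — the grouping its labels induce, with
   a lexicographic label-to-integer mapping for cross-platform
   reproducibility.
2. **Agreement.** Every pair of partitions (one per feature) is scored
   with the Adjusted Rand Index (ARI): the number of sample pairs
   co-clustered in both partitions, centered by its expectation under
   random labellings with the same marginals and scaled by its maximum.
   ARI is 1 for identical partitions (up to relabelling) and 0 in
   expectation under independence.
3. **Maximisation.** The CCC is the maximum ARI over all valid partition
   combinations, clipped below at zero. Clipping reflects that negative
   agreement carries no interpretable association signal; the coefficient
   lives in $[0, 1]$.

Because step 1 uses only ranks, the CCC is invariant under strictly
increasing transforms of either feature and equals exactly 1 for any
deterministic monotone relationship. Because step 2 compares partitions
rather than values, numeric-vs-categorical and categorical-vs-categorical
pairs need no special casing — which is what makes correlating expression
against metadata variables such as sex or cohort a one-liner.

**Assumptions and failure modes.** The CCC sees only what survives
quantile coarsening at the configured $k$ values: associations confined to
a sliver of the distribution finer than the finest partition are invisible,
and the statistic says nothing about direction or functional form. It is
also not a calibrated dependence measure across different $n$ — null
values shrink as $n$ grows — which is why significance is assessed by
permutation rather than by a fixed universal cutoff.

## Tunable parameters

* `k_range` (default `2:10`, dimensionless cluster counts). Nine
  partitions per numeric feature, the published default of the original
  statistic. Larger maxima detect finer structure at higher cost and
  higher null ceilings; the range is exposed everywhere and fixed rather
  than scaled with $n$, so results are comparable across datasets.
* `min_pairwise_samples` (default 10 samples). Below this, a quantile
  split is noise-dominated; pairs with fewer complete observations return
  `NA` rather than a meaningless number. `NA` is a sentinel, not an error,
  so one bad feature cannot abort an all-vs-all scan.
* `high_pct` / `low_pct` (default 0.30 each). The top/bottom-30% tier
  convention used by the comparison pipeline. Cutoffs are computed on
  defined coefficients only and applied inclusively, so ties at the cutoff
  never drop pairs silently.
* `n_perm`, `q` (defaults 500 and 0.99) for the pooled permutation
  threshold; `n_perm = 999` for single-pair tests, with the add-one
  p-value estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + P)$
  so p-values are never zero at finite $P$.

## Numerical and algorithmic choices

**Exact, order-independent arithmetic.** All ARI building blocks are pair
counts $m(m-1)/2$ held in doubles; every such term and every partial sum
is an integer below $2^{53}$, hence exact regardless of summation order.
The scalar expression sequence (expected index $c_a c_b / c_n$, maximum
index $(c_a + c_b)/2$) is written identically in the R reference path and
the compiled kernel, so the two backends — and any chunk size — produce
bit-identical results. The chunked "parallel" backend is a contract
(independent evaluation of condensed cells, pure assignment, no
accumulation) rather than a mandated runtime; a multi-process or GPU
realisation must pass the same bit-equivalence test.

**Degenerate cases.** When the maximum index equals the expected index
(both partitions effectively trivial) the ARI is defined as 0; such
partitions are already flagged invalid upstream (fewer than two non-empty
clusters, or $k$ exceeding the sample count), so the branch is defensive.
Argmax ties across partition combinations are broken toward the smallest
$k_x$, then the smallest $k_y$, by fixed loop order. Pairs with missing
values are handled by pairwise-complete removal *before* partitioning —
imputation would make the coefficient depend on an imputation model — and
features containing missing values take a per-pair re-partitioning path
while complete features reuse precomputed partitions.

**Permutation null.** The null reorders one feature's samples, breaking
the joint pairing while preserving both marginals — the standard
exchangeable null for association statistics. Since quantile and
categorical partitions are permutation-equivariant, null coefficients are
computed by permuting precomputed partition labels, never by
re-partitioning; this is what keeps 200 tests x 199 permutations in
seconds. The dataset-level threshold pools null draws over feature pairs
sampled uniformly with replacement and takes a quantile (default 0.99);
a per-pair null would cost quadratically more and the tiering use case
only needs a dataset-level "higher than chance anywhere" bar. In
permutation tier mode that threshold replaces the high-percentile cutoff;
the low tier stays percentile-based unless an explicit low cutoff is
given, since a pooled null bounds what is *high*, not what is *low*.

**Tiering and intersections.** Pearson and Spearman are tiered on
magnitude by default (`absolute = TRUE`): "high correlation" in the
intersection analysis means *strong*, and subgroup-reversal patterns
produce strong negative pooled coefficients that would otherwise tier
"low" for the wrong reason. Signed tiering remains available as a flag.
The five disagreement groups are exactly the tier triples with CCC high
and at least one of Pearson/Spearman low; they are enumerated in code and
tested. Degenerate all-equal coefficient vectors tier everything high
(high takes precedence at coinciding cutoffs) — deterministic, documented,
and unreachable on real data.

## What the synthetic generators emulate

The fixture module generates the relationship classes that motivate a
clustering-based coefficient, each named for the archetype it mimics:

* `monotone` — the baseline every method detects.
* `quadratic` — $y = x^2$ with sign-symmetric $x$, so the linear and rank
  coefficients are structurally zero while the relationship is
  deterministic.
* `two_group_linear` (preset `sex_dimorphic`) — linear in one group,
  constant zero in the other: a chromosome-Y gene expressed only in males.
* `simpson_reversal` (preset `mortality_simpson`) — equal positive
  within-group slopes over evenly spaced $x$, with the second group's $x$
  offset and its intercept solved in closed form so the pooled
  least-squares slope is the exact mirror of the within-group
  contribution. The reversal is guaranteed by construction, not sampled
  for: pooled-coefficient methods report the wrong sign while the CCC sees
  two tight linear bands.
* `masked_subset` — one subgroup linear, the other independent noise over
  the same range: a real relationship diluted by an unrelated subset.
* `null` — independent Gaussians, for calibration.

Noise is additive Gaussian. The default `noise_sd = 0.02` (2% of the unit
signal amplitude) was chosen once to match the near-deterministic exemplar
patterns these classes are drawn from — a dimorphic chrY gene is
essentially noise-free given sex — and the planted-matrix analyses use it
unchanged. Group sizes default to balanced (`group_fraction = 0.5`), which
is also the configuration in which a noise-free dimorphic gene scores
exactly 1 against the group label (the $k = 2$ quantile boundary coincides
with the group boundary only when groups are balanced or aligned with a
quantile cut).

What these fixtures deliberately do **not** model: RNA-seq count
distributions, library-size and normalisation effects, outlier
contamination, or correlated background structure. Passing tests on them
demonstrates the coefficient's semantics — invariances, exactness on
monotone patterns, null calibration, recovery of planted nonlinear
structure — not end-to-end performance on raw sequencing data.

## Problem sizes used in the checks

The packaged analyses run at desk scale, chosen to exercise every code
path while keeping the full suite fast: single-pair fixtures at
$n = 100$ samples; the planted-matrix pipeline at 50 features x 200
samples (1,225 pairs) over five seeds; null calibration with 200
independent pairs x 199 permutations; the pooled threshold from 500
permuted draws over 20 features; and an all-vs-all scan of 500 features x
200 samples (124,750 pairs) spot-checked bit-exactly against the per-pair
path. The p-value uniformity check compares 200 permutation p-values to
uniform with a Kolmogorov-Smirnov bound of 0.115, the simulated 99th
percentile of the KS statistic for 200 draws from the discrete uniform on
$\{1/200, \dots, 1\}$.

## Known limitations

* The quantile grid makes the coefficient's resolution depend on
  `k_range`; structure finer than the finest partition is invisible.
* Permutation thresholds are dataset-level; per-pair significance at
  all-vs-all scale would require a multiplicity strategy out of scope
  here.
* The pairwise engine materialises one partition set per feature in
  memory; at $10^5$ features this is gigabytes and would need streaming.
* `best_k` bookkeeping identifies the argmax partition pair, not a model
  of the relationship; interpretation (which subgroup drives the signal)
  comes from the metadata-correlation step, not from the coefficient.
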