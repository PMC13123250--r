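---
title: "Methods: clustering, heavy-tail models and induction scoring for fungal BGC families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, heavy-tail models and induction scoring for fungal BGC families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfkit)
```

## The analysis

Fungal genomes, particularly in the Hypocreales, carry dozens of
biosynthetic gene clusters (BGCs): contiguous regions encoding the enzymes
of one secondary metabolite. Comparative questions — which clusters are
conserved across genera, whether a family of clusters is restricted to
insect-pathogenic lineages, whether family sizes follow a power law — all
start from grouping BGCs into gene cluster families (GCFs) by
domain-architecture similarity. `gcfkit` implements that pipeline as
composable functions:

1. **Distances** between same-class BGCs from three components of domain
   architecture (presence, order, copy-level sequence similarity).
2. **Families** as connected components of the distance graph thresholded
   at a cutoff, swept over a grid to choose the cutoff.
3. **Heavy-tail models** of family sizes: discrete power law vs lognormal
   vs exponential, compared with Vuong's test and bootstrapped for
   stability.
4. **Taxonomic specificity** of families and screening for families
   exclusive to entomopathogenic genera.
5. **Induction scoring** of BGC genes from infection vs saprophytic
   RNA-seq counts.
6. A **synthetic-data generator** with known family ground truth, used to
   validate every stage end to end.

## The distance model

For BGCs $a, b$ of the same product class with ordered domain copies, the
similarity is a convex combination

$$ s(a,b) = w_J \, J(a,b) + w_A \, A(a,b) + w_D \, \mathrm{DSS}(a,b),
\qquad d(a,b) = 1 - s(a,b), $$

with

* $J$: Jaccard index of the domain-type sets (presence);
* $A$: Jaccard index of the sets of unordered adjacent domain-type pairs
  (order). A single-domain BGC has no adjacent pairs: against a
  multi-domain BGC the component is 0, against another single-domain BGC
  it is 1 exactly when the types agree;
* $\mathrm{DSS}$: for each shared domain type, copies are matched greedily
  by descending pairwise similarity (1 − normalized edit distance of the
  copy sequences; 1 when neither copy carries a sequence), and
  $\mathrm{DSS} = \sum \text{matched similarities} / (n_\text{matched} +
  n_\text{unmatched copies})$, unmatched copies counting both excess
  copies of shared types and all copies of types present on one side only.

Cross-class pairs are never formed; each class is clustered independently.

**Weights.** The defaults $(w_J, w_A, w_D) = (0.2, 0.05, 0.75)$ put most
weight on copy-level similarity, the component that actually separates
related clusters once they share domain content. They are plain
configuration (`similarity_weights()`), not a fitted quantity.

**Greedy vs optimal matching.** Greedy matching is deterministic (ties
break by input order of the copies) and exact when each shared type occurs
once per BGC. With repeated copies it can fall below the optimal
assignment; matching theory bounds the greedy weight at no less than half
the optimum, and the test suite compares greedy against an exhaustive
matching oracle on small instances — the observed gap on random instances
is below 0.05. No anchor-domain boosting or glocal alignment mode is
implemented.

## Families and the cutoff sweep

Families at cutoff $c$ are the connected components of the graph with an
edge wherever $d \le c$ (union-find; a BFS oracle and igraph cross-check
the implementation in the tests). Distances are computed once; the sweep
over the default grid $0.1, 0.2, \ldots, 0.9$ sorts edges by distance and
merges incrementally, snapshotting the partition at each grid point. This
makes the nestedness of the partitions — finer at lower cutoffs —
structural rather than incidental, and the monotonicity of the reported
metrics (families and singletons non-increasing, mean family size
non-decreasing in the cutoff) follows.

The `knee` policy of `select_cutoff()` formalizes the visual rule of
picking the last cutoff before mean family size explodes: the grid point
with maximal perpendicular distance to the chord joining the endpoints of
the pooled mean-size curve, ties broken toward the smaller cutoff (so a
featureless linear curve yields the smallest grid point). A `fixed`
policy is available for reproducing a pre-chosen cutoff such as 0.6.

A singleton is a family of size one — equivalently a BGC not grouped with
any other. The MiBIG annotation is carried as a boolean flag per BGC;
`gcf_size_table(..., mibig_only = TRUE)` restricts size distributions to
families containing at least one flagged member.

## Heavy-tail models of family sizes

Three discrete models are fitted to the sizes $k \ge x_{\min}$:

* power law $p(k) = k^{-\alpha} / \zeta(\alpha, x_{\min})$, $\alpha$ by
  MLE on $(1, 20]$. The Hurwitz zeta normalizer is computed by direct
  summation of $10^4$ terms plus an Euler–Maclaurin tail correction
  (verified against an independent Riemann-zeta implementation to
  $10^{-10}$);
* lognormal and exponential obtained by evaluating the continuous density
  at the integers and renormalizing over $k \ge x_{\min}$. The
  normalizing sum runs to a truncation bound (ten times the largest
  observation, at least $10^4$) with the continuous upper-tail mass added
  as a correction, all in log space to avoid underflow at extreme
  parameters during optimization.

With `xmin = "auto"` the power-law step tries every observed value
leaving a tail of at least 10 observations and keeps the one minimizing
the Kolmogorov–Smirnov distance between empirical and fitted tail CDFs;
`compare_models()` then applies that common $x_{\min}$ to all three
models, because Vuong's test requires identical support and observation
vectors.

**Vuong's test.** With per-observation log-likelihood differences $d_i$,
the statistic $\sum d_i / (s_d \sqrt n)$ is asymptotically standard
normal under model equivalence; the p-value is two-sided, and a verdict
("favored" model) is issued at 0.05 by default — the threshold is a
parameter, not a claim. Degenerate comparisons ($s_d = 0$, identical
models) return statistic 0 and p 1. Parameter stability is assessed by a
nonparametric bootstrap (default 1,000 replicates; percentile 95%
intervals; replicate failures on degenerate resamples are counted and an
error is raised past 50%).

Fits flag, rather than silently return, parameters at the search bounds.
Note the lognormal can mimic a power law over finite samples: on
power-law data the expected outcome is non-rejection, not a power-law
victory.

## Specificity and exclusivity

Families are classified as `singleton`, `genus_specific` (≥ 2 members,
one genus) or `multi_genus` — three categories, hence the df = 2
goodness-of-fit chi-square. The null is uniform over categories by
default and is exposed as a parameter, since competing backgrounds (for
example the all-species genus distribution) are equally defensible.

Exclusivity screening keeps families whose members span at least three
distinct entomopathogenic genera (default list: *Metarhizium*,
*Beauveria*, *Cordyceps*, *Hirsutella*, *Tolypocladium*,
*Purpureocillium*, *Akanthomyces*, editable) and include no member from
any other genus. A single member from a non-entomopathogenic genus
disqualifies the family. `genus_cooccurrence()` counts, per unordered
genus pair, the exclusive families containing both.

## Expression scoring

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes with no zero anywhere; the implementation is checked
against DESeq2's `estimateSizeFactorsForMatrix` in the tests), then
transformed as $\log_2(\text{count}/sf + 1)$. This transform is a
monotone, variance-flattening approximation — deliberately not a
dispersion-trend VST, which would change no rank-based or
difference-of-means conclusion downstream. The induction score of a gene
is the mean transformed expression in infection samples minus the mean in
saprophytic controls, reported per host where hosts are annotated and
pooled; a BGC's score is the mean over its member genes, with backbone
genes flagged (and marked `*` in the exported heatmap matrices). No
significance threshold is imposed: scores are reported and thresholds are
left to the caller.

## What the generator emulates — and what it does not

`simulate_dataset()` plants ancestral families with class labels drawn
from the empirical class abundances of Hypocreales BGC surveys, family
sizes from a configurable heavy-tail law (lognormal $\mu = 1$, $\sigma =
0.8$ by default, reflecting the lognormal verdict on real family sizes),
a home genus per family with members placed there with probability 0.85
(the genus-specific-majority pattern), per-genome Poisson orphans, and
genome sizes weakly increasing in BGC count. Prototype architectures of
the same class draw domain tokens without replacement from a shared pool,
so inter-family distance is 1 by construction and a `min_separation`
floor (default 0.8) is verified defensively; members are mutated copies
(token substitutions and residue substitutions at `mutation_rate`, domain
indels at `indel_rate`). Default sizes — 12 genera × 4 species, 40
ancestral families, around 200 BGCs — keep a full sweep under a couple of
seconds while leaving every class populated.

The generator is deliberately not phylogenetically explicit: no gene
gain/loss on a tree, no horizontal transfer, no correlated domain
evolution, and inter-family similarity is near zero rather than graded.
Passing recovery tests therefore demonstrates correctness of the
clustering machinery under separable ground truth, not clustering
accuracy on real antiSMASH/BiG-SCAPE output, where family boundaries are
genuinely fuzzy. Likewise the count simulator (negative binomial,
gene-wise lognormal baselines, planted fold change on induced genes)
validates score recovery, not differential-expression inference.

Because no quantitative within-family identity level is established for
real data, the generator exposes `mutation_rate` rather than asserting
one; at the 0.03 default, within-family distances stay well below 0.1
and recovery at the knee-selected cutoff is essentially exact (ARI >
0.95 across seeds).

## Numerical and design choices

* Unknown class labels are rejected at load time, never coerced: the
  seven-class vocabulary partitions every downstream analysis.
* Coordinates, when present, are 1-based inclusive and only carried.
* Family ids are `<class>_<integer>` numbered by each family's smallest
  member id, so labels are stable under record shuffling.
* The chi-square test errors on an expected count of zero rather than
  returning a misleading statistic.
* Problem sizes in the test suite (50 sweep datasets of ≲ 100 BGCs,
  10,000-draw recovery samples, 200 bootstrap replicates) were chosen as
  the smallest sizes at which the checked properties are stable.
* `set.seed` governs every stochastic routine through explicit `seed`
  arguments; identical seeds reproduce identical outputs byte for byte.

## Known limitations

* The DSS uses plain normalized edit distance on short per-copy strings;
  real domain sequences would warrant alignment-based scoring.
* Connected components have no clan-level affinity refinement; a single
  spurious low-distance edge can chain two families (mitigated here by
  prototype separation, present in real data).
* The lognormal/exponential discretization integrates the continuous
  density at integer support; for very small $x_{\min}$ and heavy
  contamination the rounding-based and density-based discretizations
  differ slightly.
* Automatic $x_{\min}$ selection uses the KS criterion only; no
  semi-parametric goodness-of-fit p-value is computed.
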