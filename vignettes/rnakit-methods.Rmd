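---
title: "rnakit: statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rnakit: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnakit)
```

This vignette documents the statistical models behind each rnakit module,
the reasoning for parameter defaults, and the numerical and design choices
that affect results. The companion README shows a worked end-to-end
example; here the emphasis is on *why* each method behaves as it does.

## 1. Data model

The package is organized around two validated S4 containers:

* `CountMatrix` — a numeric feature × sample matrix with unique, non-empty
  row and column names, non-negative finite values, and a `normalized`
  flag. Raw matrices must be (near-)integer counts.
* `DiffExpTable` — per-feature differential-expression results
  (`log2fc`, `pval`, `padj`) keyed by unique feature IDs.

Every filtering or normalization operation appends a structured record to
the table's history (operation name, parameters, feature counts, extra
info). `undoLast()` replays the history minus its last step through the
operation registry, so undo is *reconstructive*: it re-applies the
recorded operations to the original loaded state rather than caching
snapshots. This keeps memory flat and guarantees that an undone object is
bit-identical to one produced by running the shorter pipeline directly —
a property the test suite verifies for both count matrices and DE tables.

## 2. Normalization

### Median of ratios

For counts $k_{ij}$, the size factor of sample $j$ is
$\hat s_j = \operatorname{median}_i \left( k_{ij} / \big(\prod_v k_{iv}\big)^{1/m} \right)$,
taken over features positive in **all** samples (an error is raised when
no such feature exists, since the estimator is undefined). We take the
median of the ratios themselves, not the exponentiated median of log
ratios; for an even number of usable features the two differ slightly
(the arithmetic versus geometric mean of the two central order
statistics), which is why cross-checks against other implementations use
a 1e-4 tolerance rather than exact equality.

A consequence worth knowing: multiplying one sample's counts by $c$
rescales its factor by $c^{1-1/m}$ (the geometric means move too), so
equivariance holds *exactly on factor ratios* — $\hat s_j/\hat s_{j'}$
scales by $c$ — and only approximately on individual factors. Tests
assert the ratio form.

### Trimmed mean of M-values (TMM)

The reference sample is the one whose upper-quartile/library-size ratio
is closest to the mean of those ratios. For each other sample $k$,
M-values $M_i=\log_2\frac{k_{ik}/N_k}{k_{ir}/N_r}$ and A-values
$A_i=\tfrac12\log_2\frac{k_{ik}}{N_k}\frac{k_{ir}}{N_r}$ are computed on
features positive in both samples; features are discarded if their rank
on $M$ falls in the outer 30% on either side, or their rank on $A$ in
the outer 5% (`logratio_trim = 0.3`, `abs_trim = 0.05`; the trim indices
are `floor(n*trim) + 1` to `n + 1 - that` on the ranks, so the kept set
is deterministic even with ties). The factor is
$2^{\sum_i w_i M_i / \sum_i w_i}$ with the delta-method binomial weight
$w_i = \frac{N_k - k_{ik}}{N_k k_{ik}} + \frac{N_r - k_{ir}}{N_r k_{ir}}$
used **directly** as the weight. Note this is an approximate *variance*,
so some implementations weight by its inverse (precision weighting);
rnakit's formula intentionally uses $w_i$ itself, which down-weights
high-count features. The two variants agree on symmetric data, agree in
direction under composition shifts, and correlate > 0.95 in practice,
but are not numerically identical; the test suite therefore checks
rnakit against an independent step-by-step re-derivation at 1e-12 and
against edgeR only qualitatively. Factors are renormalized to geometric
mean 1.

### CPM and quantile normalization

`cpmFactors()` scales each column to exactly $10^6$ total (column sums
after normalization equal 1e6 to machine precision). Quantile
normalization replaces each column's order statistics with the row means
of the sorted matrix; ties within a column receive the mean of the
rank-values they span, so the classic "all sorted columns identical"
property holds exactly only for tie-free input.

### Power transform + standardization

`powerTransformStandardize()` runs, per sample, a Box–Cox transform of
`value + 1` with the per-sample maximum-likelihood $\lambda$ (golden-
section search on the profile log-likelihood), then standardizes each
**sample** (column) to mean 0 / sd 1, then z-scores each **feature**
(row). The column standardization makes the output invariant, up to
numerical tolerance, to per-sample rescaling of the raw counts
(row-profile correlations ≥ 0.999 under 10× library-size distortions),
which is what makes the result safe to feed into expression-pattern
clustering. Zero-variance rows are mapped to 0 and flagged in the
history record (`info$degenerate`) rather than producing NaNs.

## 3. Distances for expression profiles

Besides Euclidean and the usual correlation distances
($1-r$ for Pearson/Spearman, $1-\cos$), two families target time-course
data:

* **YS1 / YR1**: $d = 1 - [w_1\,\tfrac{\rho+1}{2} + w_2 A + w_3 M]$,
  where $\rho$ is Spearman (YS1) or Pearson (YR1) correlation, $A$ is
  the fraction of matching consecutive slope signs, and $M$ is a
  min-max-position agreement score. Default weights
  `c(0.5, 0.25, 0.25)` must be non-negative and sum to 1 (validity-
  checked). YS1 is invariant to strictly increasing transforms of
  either profile; both are 0 for proportional profiles and 1 for
  perfectly opposed monotone ones.
* **Jackknife correlation**: $1 - \min_i r(x_{-i}, y_{-i})$, the most
  pessimistic leave-one-out Pearson correlation. This discounts
  correlations driven by a single time point; tests verify it against
  direct enumeration.

## 4. Clustering

`runClusterer()` dispatches to k-means, k-medoids (PAM on any supported
distance), agglomerative hierarchical clustering (average/complete
always; Ward only with Euclidean distances, since Ward's objective is
defined on squared Euclidean geometry), and a self-contained HDBSCAN
(mutual-reachability minimum spanning tree, condensed tree, excess-of-
mass cluster selection; `min_cluster_size` default 5). k-means with
`k = n` is special-cased to singleton clusters because the base
implementation refuses that boundary.

### Gap statistic

Model selection compares $\log W_k$ of the data to that of `n_refs`
uniform reference sets drawn in the PCA-aligned bounding box of the
data. The chosen $k$ is the **first** $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$ (the one-standard-
error rule). A known property of the first-crossing rule: with weak or
borderline separation, $\mathrm{Gap}(1) \ge \mathrm{Gap}(2)-s_2$ can
hold by chance and yield $k=1$ even when a larger $k$ has a far higher
gap; the rule is kept as stated because it is the standard estimator,
and the documentation (and tests) use clearly separated data when a
specific $k$ is the expected answer.

### CLICOM ensemble

`clicomEnsemble()` combines heterogeneous base clusterings:

1. Each base solution (possibly with noise labels `-1`) votes into an
   evidence-accumulation matrix $E_{uv}$ = fraction of solutions
   placing $u$ and $v$ in the same cluster (noise points co-cluster
   with nothing; the diagonal is 1).
2. Each base *cluster* becomes a block; blocks are vertices of a graph
   with edges between blocks whose overlap ratio exceeds the evidence
   threshold; maximal cliques of that graph are candidate consensus
   clusters (a clique = a set of mutually agreeing blocks).
3. A feature joins a candidate if it appears in at least
   `evidence_threshold` of the clique's blocks; membership conflicts
   are resolved toward the candidate with the higher mean evidence
   linking the feature to the cluster's current members.
4. Clusters below `min_cluster_size` are dropped; with
   `attach_unclustered = TRUE`, leftover features are attached to the
   cluster with the highest mean evidence, provided that evidence
   exceeds the threshold — otherwise they stay noise (`-1`).

The departure from plain evidence-accumulation ensembles is step 2–3:
consensus clusters are built from cliques of *whole blocks* rather than
by re-clustering $E$, which lets tight agreement among a subset of
solutions survive disagreement elsewhere, and naturally supports
ensembles whose members have different $k$ (the default demo mixes
$k=3$, $k=4$, and density-based members). Labels are invariant to
permuting the base solutions' label alphabets, and `min_cluster_size`
is enforced unconditionally — both property-tested.

## 5. Enrichment

* **Hypergeometric**: upper-tail `phyper(x - 1, n, M - n, N)`; exact.
* **Permutation**: draws `repeats` random test sets of the same size
  from the background and reports $p = (s + 1)/(r + 1)$ where $s$
  counts permutations with overlap **at least** the observed one (ties
  count as successes). The +1 correction makes the estimator valid
  (never anti-conservative) at any `repeats`; the suite checks both
  agreement with the exact tail within 3 Monte-Carlo standard errors
  and conservativeness under the null.
* **ELIM decorrelation** (`goEnrichmentElim`): terms are tested
  children-first (reverse topological order); whenever a term is
  significant at `elim_alpha` (default 0.01, raw scale), its annotated
  test genes are eliminated from all ancestors before those are tested.
  `elim_alpha = 0` disables elimination and reproduces the classic
  per-term test exactly — a relationship the tests exploit. Adjustment
  defaults to Benjamini–Yekutieli because the per-term p-values on a
  DAG are dependent in an uncontrolled way.
* **mHG / XL-mHG** (`mhgTest`): the statistic is the minimum
  hypergeometric tail over all prefixes of the ranked list (optionally
  constrained by `x_min`/`l_max`); its exact p-value is computed by the
  $O(M^2)$ dynamic program over paths in the rank grid, counting the
  probability that a random placement of the positives achieves a tail
  ≤ the observed statistic. Intermediate path weights are rescaled by
  1e250 blocks to avoid underflow. The suite validates against full
  enumeration of all placements for $M \le 10$.
* **Continuous attributes**: rank-based comparison of the attribute
  values of the test set against permutation draws, with the same
  $(s+1)/(r+1)$ estimator.

`adjustPvalues()` implements BH, BY and Bonferroni directly (step-up
with running cumulative minima); it is tested against an independent
oracle and used for all tabular outputs.

## 6. Pipelines and the operation registry

A `Pipeline` is a named list of `(op, params)` steps. Every op lives in
a registry entry carrying the applicable table kinds, the implementing
function, and a validator; `pipelineAdd()` validates **at add time**
(unknown op, unknown/unnamed parameters, out-of-range values all fail
immediately, not at run time). Pipelines serialize to JSON or YAML with
a `version` tag; import re-validates every step and refuses files with
a newer major version, missing version, or any invalid step. Non-
serializable parameter values (e.g. S4 objects) are rejected at export.
Applying a pipeline to several tables stops at the first failing table,
keeps earlier results, and reports per-table status.

## 7. Synthetic data generators

Generators are first-class, deterministic (seed mandatory in
`simSpec()`), and used by the test suite as ground truth:

* `simulateCounts()` — negative-binomial counts with planted cluster
  profiles (cluster mean shapes × library sizes; dispersion is the NB
  `1/size`). Returns the matrix and the planted labels; with moderate
  dispersion the planted structure is recoverable with ARI > 0.9 by
  the package's own clustering stack, and per-cluster column means
  converge to the profile shapes (law-of-large-numbers tests).
* `simulateDiffExp()` — a DE table with known up/down/null truth at
  `de_fraction` and `effect_size`; null features have uniform p-values
  (checked: rejection rate within Monte-Carlo bounds of $\alpha$).
* `simulateOntology()` — a random DAG of the requested depth plus gene
  annotations, written both as in-memory objects and as OBO/GAF files
  that round-trip exactly through `readObo()`/`readGaf()`. Every
  generated graph is acyclic by construction (levels only point
  upward), verified over many seeds.

Scope: generators target correctness testing at small-to-moderate sizes
(hundreds to low thousands of features), not realistic transcriptome-
scale benchmarks — no gene-length effects, GC bias, batch structure, or
correlated dispersion trends.

## 8. Numerical choices

* All seeded code paths use an internal `withSeed()` that saves and
  restores the RNG state, so library calls never perturb user RNG.
* mHG dynamic programming rescales by 1e250 to stay in double range up
  to $M$ in the thousands.
* Box–Cox $\lambda$ is found by golden-section search on
  $[-2, 2]$ to a 1e-6 bracket; $| \lambda | < 10^{-8}$ falls back to
  the log branch.
* BH/BY use `cummin` from the largest p downward; results are clamped
  to $[0, 1]$.
* Gap statistic reference draws use one RNG stream per call (seeded),
  so `chosen_k` is reproducible.

## 9. Problem sizes and limitations

The package is designed for matrices up to roughly $10^4$ features ×
$10^2$ samples on a single core. Known limitations: exact mHG is
quadratic in list length (use `x_min`/`l_max` for very long lists);
CLICOM's clique enumeration can grow quickly if the evidence threshold
is set so low that the block graph becomes dense; HDBSCAN here is a
straightforward $O(n^2)$ implementation; and the TMM weighting choice
described in §2 means factors are close to, but not interchangeable
with, other TMM implementations. DE testing itself (model fitting) is
out of scope — the package consumes DE tables rather than producing
them, except via the synthetic generator.
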