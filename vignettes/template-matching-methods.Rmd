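---
title: "Matching, merging and scoring cell populations across cytometry samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching, merging and scoring cell populations across cytometry samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotemplates)
```

## The problem

A flow cytometry sample is an `n x p` matrix: `n` cells measured on `p`
channels (scatter plus fluorescence-tagged protein markers). Within one
sample, cells group into populations — helper T cells, cytotoxic T cells, B
cells, NK cells, and, in leukemia samples, immature blasts. Most scientific
questions, however, live *across* samples: are the populations of subject A
stable across days? Does a new patient sample carry a population that
healthy samples never show? Answering these requires registering
populations across samples, which is hard because populations shift, split,
merge, appear and disappear between samples.

`cytotemplates` treats every population as a Gaussian summary
\((\mu, \Sigma, n)\) and works entirely on those summaries after
clustering. The pipeline is:

1. **Variance stabilization** — per channel, an `asinh(z/c)` transform with
   the cofactor `c` chosen to make within-population variances homogeneous.
2. **Clustering** — k-means per sample with the number of clusters chosen
   by a consensus of five validity indices.
3. **Matching** — a minimum-cost *mixed edge cover* (MEC) registers
   clusters across two samples; its cost is the sample dissimilarity
   `D(A, B)`.
4. **Templates** — hierarchical matching-and-merging (HM&M) builds a binary
   tree over a cohort; internal nodes hold *meta-clusters* (pooled matched
   clusters) and serve as class templates.
5. **Classification** — nearest-template assignment, plus a piecewise
   scoring function for cohorts where a minority class carries extra
   blast-like populations.

## Variance stabilization

Fluorescence variance grows with mean intensity, so bright populations
spread more than dim ones and no single distance treats them comparably.
For each channel the package transforms `z` to `asinh(z/c)` and scans a
log-spaced grid of cofactors (default 30 points in `[1, 1e5]`). For each
candidate, one-dimensional density peaks are located per sample (kernel
density estimate with Silverman's bandwidth; modes must reach 5% of the
density maximum and have 5% prominence — the knobs are arguments), peak
variances and sizes from all samples are pooled into one list, and
Bartlett's likelihood-ratio statistic of that pool is computed. The
returned cofactor minimizes the statistic; ties go to the smallest
cofactor so the result is deterministic. The same cofactor applies to the
channel in every sample — cross-sample comparability is the point.

Zero-variance peaks are dropped from the pool (their log is undefined) and
candidates with fewer than two pooled peaks score zero and are flagged.

```{r cofactor, eval = FALSE}
profile <- select_cofactor(samples, channel = "CD4")
transformed <- lapply(samples, asinh_transform,
                      cofactors = c(CD4 = profile$best_cofactor))
```

## Choosing the number of clusters

Each candidate `k` is fit by k-means and scored with average silhouette
width, Calinski–Harabasz, Dunn, S_Dbw and Davies–Bouldin. The first three
vote for their argmax, the last two for their argmin; the consensus is the
majority vote with ties broken toward smaller `k` (fewer populations is
the conservative reading). The quadratic-cost indices run on a seeded
subsample of at most 5,000 cells.

k-means uses 10 restarts seeded by k-means++ (each new center drawn with
probability proportional to squared distance from the chosen ones).
Plain random restarts are unreliable when one population holds most of the
cells — a common situation in leukemia samples, where blasts can exceed
half the sample — because several centers land in the dominant population
and the minority populations merge; distance-proportional seeding removes
this failure mode without changing the objective.

Cluster summaries use the maximum-likelihood covariance (divisor `n`) with
a small ridge, `Σ + ε I` where `ε = 1e-6 · trace(Σ)/p` (floor `1e-12`), so
pooled covariances stay invertible even for singleton clusters.

## Matching: the mixed edge cover

Given cluster lists `A` (size `k_a`) and `B` (size `k_b`) and a
dissimilarity `d`, a mixed edge cover lets every cluster be matched to one
*or more* clusters on the other side, or stay unmatched at a fixed penalty
`λ`. The cover minimizes

$$\sum_{(i,j) \in \text{edges}} d(a_i, b_j) \;+\; \lambda \cdot \#\{\text{unmatched}\},$$

so split populations match many-to-one, and genuinely missing populations
pay `λ` instead of being forced onto a bad partner. The minimum cost is
the sample dissimilarity `D(A, B)`; it is symmetric and at most
`λ(k_a + k_b)`.

The default `d` is the pooled-covariance Mahalanobis distance

$$d(c_1, c_2) = \sqrt{\tfrac12 \Delta^\top \Sigma_p^{-1} \Delta},
\qquad \Sigma_p = \frac{(n_1-1)\Sigma_1 + (n_2-1)\Sigma_2}{n_1+n_2-2},$$

with `Δ = μ₁ − μ₂`. A squared variant (no square root) is available via
`dissimilarity_config(squared = TRUE)`; under the squared form the default
penalty `λ = p` has the clean reading that two clusters match only when
their average squared deviation per dimension is below one. Both
conventions are offered because the two readings circulate; the square
root is the package default and all defaults are internally consistent
with it. Symmetrized Kullback–Leibler and Euclidean center distance are
the alternatives. Mahalanobis and symmetrized KL are invariant under
invertible affine maps of the measurement space; the Euclidean center
distance is not, which is exactly why it mis-groups samples whose
populations differ in spread — the package keeps it only for comparison.

### Exactness

The solver is exact. An optimal cover can always be arranged as
vertex-disjoint stars (if two adjacent vertices both had degree two the
connecting edge could be dropped without uncovering anything), so the
problem reduces to a square assignment problem: every vertex either joins
the one-to-one core matching or pays `min(λ, d_min)` — stay unmatched, or
ride along as an extra satellite of its nearest partner. Dummy rows and
columns price that choice, and an `O(n³)` Hungarian algorithm solves the
assignment; cluster counts are a few tens, so this costs microseconds. The
test suite validates the solver against brute-force enumeration over all
edge subsets on thousands of random instances, and checks the resulting
bound `d(c, \text{mec}(c)) ≤ 2λ` for every covered cluster (an edge
costlier than two penalties would never be kept).

Tie-breaking: when several covers share the minimum cost, the solver's
deterministic output is reported; the cost, not the edge set, is the
contractual result.

## Templates: hierarchical matching and merging

`build_template_tree()` starts with every clustered sample as an orphan
leaf, computes all pairwise `D`, and repeatedly merges the closest pair of
orphans; the new node's height is their dissimilarity, and ties go to the
lexicographically smallest node-id pair, making rebuilds bit-identical.
Merging pools matched clusters into meta-clusters: connected components of
the cover's edge set (chains through shared partners collapse into one
component — the unique closure of "a cluster together with its matched
set"), with unmatched clusters carried over as singleton meta-clusters.
Meta-cluster parameters are the maximum-likelihood estimates for the
pooled cells, computed from the summaries by moment matching:

$$\mu = \frac{\sum_i n_i \mu_i}{n}, \qquad
\Sigma = \frac{\sum_i n_i (\Sigma_i + \mu_i \mu_i^\top)}{n} - \mu\mu^\top.$$

These equal a single-Gaussian ML fit to the concatenated cells exactly, so
no raw cells need to be retained. Cell counts are conserved from leaves to
root, and provenance records make per-meta-cluster sample participation
computable at any level. Height inversions (a child higher than its
parent) are possible because merged nodes change, and are allowed but
flagged; Newick export clamps the corresponding branch lengths at zero
with a warning.

`cut_templates()` turns the tree into class templates three ways:
`by_labels` (maximal single-class nodes, given metadata), `by_height`, and
`by_gap`, which places the cut at the largest ratio between consecutive
sorted merge heights. "Well-separated branches" has no canonical
quantitative definition, so the relative-gap rule — the standard
dendrogram heuristic — is the default and is overridable.
`insert_sample()` updates templates dynamically: a new sample merges into
the nearest template when within a threshold (default: the root height of
the tree the set was cut from, the scale at which everything eventually
joins) and founds a new template otherwise. No rebalancing is attempted;
insertion order can matter near the threshold, which is inherent to
incremental updates.

## Classification and the piecewise score

`nearest_template()` assigns a sample to the least dissimilar template,
with an optional rejection threshold for "new class" detection. For
two-class cohorts of the leukemia type, `disease_specific_metaclusters()`
registers the positive template `T⁺` against the negative template `T⁻`
with a MEC; the unmatched `T⁺` meta-clusters form `M⁺`, the populations
with no healthy counterpart. `score_sample()` then computes two
independent covers (sample vs `T⁺`, sample vs `T⁻`); for cluster `c_i`
with `d` the average distance to its matched set and similarity
`s = 2λ − d ≥ 0`:

* `f⁺ = s` if the match meets `M⁺`; `−s/k` if matched only to shared
  meta-clusters; `0` if unmatched (`k` = number of clusters in the
  sample);
* `f⁻ = −s/k` if matched in `T⁻`; `+λ` if unmatched there;

and the sample score is the abundance-weighted sum
\(f(X) = \sum_i \frac{|c_i|}{|X|}\,\frac12 (f^+ + f^-)\), positive iff the
sample is called diseased. The asymmetry is deliberate: the positive
branch of `f⁺` is not divided by `k`, so one well-matched disease-specific
population outweighs several shared ones, trading false positives for
fewer false negatives — the sensible direction for a screening score. A
score of exactly zero classifies as negative (the positive call requires
positive evidence). The two covers are computed independently rather than
as a joint three-way problem; a cluster may therefore match in both
templates, which the score handles by construction.

Panel (tube) scores combine by a plain mean over a user-chosen subset;
panel selection is configuration, not automation. Empirical p-values
against a null score distribution (e.g. an isotype-control panel) use the
add-one rule `p = (1 + #{null ≥ score}) / (1 + #null)`. Evaluation metrics
report `NA` for empty denominators rather than zero.

## The synthetic cohort generator

Because the real cohorts behind this class of methods are external
datasets, the package ships a generator that reproduces their *structure*
with ground truth at every level. Populations are Gaussian (the model
class the matching assumes), drawn with Dirichlet-perturbed mixture
weights (concentration 5000, keeping weight wiggle under about one
percentage point so empirical fractions track their targets within 2% at
`n = 10⁴`) and per-population mean shifts at each design level.

* `simulate_hd_cohort()`: healthy-donor style; default 5 subjects × 1 day
  × 5 technical replicates = 25 samples of 2,000 cells, four
  lymphocyte-like populations in five channels with means at least 8
  pooled-σ apart, and shift scales `subject 2 ≫ day 0.5 ≫ replicate 0.1`
  so the subject grouping is recoverable from the tree. Larger designs
  (more days/replicates, as in real repeated-measure cohorts) are
  parameters, not code changes.
* `simulate_disease_cohort()`: default 200 negatives + 30 positives of
  1,000 cells; both classes share the four populations, every positive
  adds a blast-like population at 20–60% abundance placed ≥ 5σ from all
  shared ones, and positives get twice the between-sample shift spread of
  negatives (diseased cohorts are the more heterogeneous ones). A
  stratified 50/50 train/test split is returned.

These sizes keep the full pipeline — per-sample consensus clustering,
template building for both classes, `M⁺` detection and scoring of all
held-out samples — at a few minutes on one core, which is the problem
scale the package's own validation uses.

What the generator does **not** emulate: spectral spillover at the raw
level, doublets and debris, dead cells, heavy-tailed or skewed populations
(a contamination flag exists on request via custom `population_spec`
covariances), or realistic marker panels. Passing tests on these cohorts
therefore demonstrate the correctness of the matching/merging/scoring
machinery under its own model assumptions — Gaussian, well-separated
populations — not robustness to every artifact of instrument data.

## Numerical choices, in one place

* Covariance ridge `1e-6 · trace/p`, floor `1e-12`; keeps every
  Mahalanobis solve well-posed.
* Spillover matrices must be column-stochastic to `1e-6` and are rejected
  when the condition number exceeds `1e8`.
* Bartlett: zero-variance groups dropped with a warning; fewer than two
  groups returns 0 (homoscedasticity trivially satisfied).
* Cofactor grid ties → smallest cofactor; merge ties → smallest node-id
  pair; nearest-template ties → smallest template index; score 0 →
  negative.
* Peak finding below 50 values, or on constant input, returns a single
  peak spanning everything.
* Index subsample cap 5,000 cells, seeded; all RNG flows from explicit
  seed arguments.

## Known limitations

* k-means with a validity-index consensus assumes roughly convex,
  separated populations; rare populations below the index resolution can
  be absorbed, and downstream matching cannot recover what clustering
  merged (the failure mode is visible as chained meta-clusters).
* The MEC solver is exact but `O((k_a+k_b)³)`; fine for tens of clusters
  per sample, not intended for hundreds.
* Template trees use all `O(N²)` pairwise dissimilarities; cohorts of
  hundreds of samples are fine, tens of thousands would need the
  accelerated variants deliberately left out of scope.
* FCS support is read-only, list-mode, versions 3.0/3.1, float or uniform
  16/32-bit integer data.
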