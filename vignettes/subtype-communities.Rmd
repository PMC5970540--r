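---
title: "Reconciling consensus clusterings into subtype communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling consensus clusterings into subtype communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polyrecon)
```

## The problem

Molecular subtyping of a tumor cohort from a genes × samples expression
matrix is notoriously algorithm-dependent: hierarchical clustering (HC),
k-means (KM) and non-negative matrix factorization (NMF) each impose
different cluster shapes and objectives, and they routinely disagree on both
the number of clusters *k* and the assignment of samples. polyrecon treats
this disagreement as signal rather than nuisance. Each algorithm is run as a
subsampled consensus clustering; the chosen per-algorithm solutions are then
*reconciled*: every cluster becomes a node in a weighted network, edges
quantify cross-algorithm cluster overlap, and community detection on that
network groups mutually overlapping clusters into "subtype communities".
Clusters that every algorithm finds, at whatever granularity, end up in the
same community; algorithm-specific fragments are absorbed into the robust
structure they overlap.

## The procedure

1. **Variance filtering.** Genes with sample standard deviation (unbiased,
   n−1 denominator) above a threshold are retained; 0.8 is the conventional
   default for log-scale intensities.
2. **Consensus clustering.** For each algorithm and each *k* in 2..10, the
   base clusterer runs on `resamplings = 100` random subsamples of
   `fraction = 0.8` of the samples (without replacement). The consensus
   matrix entry for a sample pair is the fraction of jointly sampled runs in
   which the pair co-clustered. Distances are Euclidean; linkage is average,
   both inside the resampling loop and when the consensus matrix itself is
   clustered (`1 − consensus`) to produce the algorithm's final labels.
3. **Scoring and choice of k.** Each (algorithm, k) is scored with the
   cophenetic correlation coefficient of the consensus dissimilarity and the
   mean silhouette width of the final labels on it. The user may fix *k* per
   algorithm; the automatic rule returns the largest *k* whose two scores
   are both within `eps = 0.01` of that algorithm's maxima — a reproducible
   rendering of "prefer the finest stratification whose quality is
   approximately as good as the best". Real cohorts often warrant judgment
   calls (consensus-matrix inspection, outlier counts) that no such rule can
   encode, which is why explicit mode exists and is the default interface.
4. **Reconciliation networks.** For every cross-algorithm cluster pair we
   compute (a) the upper-tail hypergeometric probability of the observed
   overlap, BH-adjusted jointly over all pairs ("HYP"), and (b) the
   proportion of maximum intersection `PMI = |A∩B| / min(|A|, |B|)`. HYP
   keeps edges with FDR < 0.05, weighted by `−log10(FDR)`; PMI keeps edges
   with PMI ≥ 0.1, weighted by the PMI itself.
5. **Community detection.** Weighted asynchronous label propagation: nodes
   start with unique labels and, visited in seeded random order, repeatedly
   adopt the label with the largest incident weight sum until stable.
   Samples are then assigned by one-vote-per-algorithm majority over the
   communities of their clusters.
6. **Selection.** Both reconciliations are scored by the mean silhouette
   width of the sample-level communities on the filtered expression matrix
   (Euclidean by default, `1 − Pearson` by flag); the higher mean wins,
   ties go to HYP.
7. **Downstream.** Community enrichment against known labels (per-cell
   hypergeometric FDR plus a seeded Monte-Carlo chi-square global test),
   per-community shrunken centroids with Pearson-correlation assignment of
   validation samples, and Kaplan–Meier / log-rank survival comparison.

## Design decisions in detail

**Edge weights in HYP mode.** FDR values themselves make weak overlaps
dominate a maximum-weight rule, so propagation uses `−log10(FDR)` (floored
at 10^−300). This preserves the intended ordering — smaller FDR, stronger
tie — and is the one place where the network construction is an
interpretation rather than a mechanical recipe.

**BH pooling.** All cross-algorithm pairs form one hypothesis family; the
adjustment is pooled over the whole network rather than per algorithm pair.

**Sample-to-community rule.** Sample-level community membership is needed
for silhouettes, enrichment and survival, but is not determined by the
cluster-level communities alone. We use majority vote (one vote per
algorithm), breaking ties toward the candidate community whose voting
clusters hold the most samples, then toward the lowest community id. The
rule is deterministic and reduces to the obvious answer whenever a sample's
clusters agree.

**When reconciliation changes granularity.** A property worth stating
explicitly: if all algorithms return *identical* partitions, both networks
are perfect matchings and the communities are exactly those clusters —
reconciliation never merges disjoint clusters that every algorithm agrees
on. Merging happens precisely when algorithms disagree: when one
algorithm's clusters are unions of another's (the nested case, where PMI
parent edges are exactly 1), or when forced over-clustering fragments
robust groups differently per algorithm. Consequently, on synthetic data
whose planted sub-clusters are strong enough that every algorithm recovers
them identically, the pipeline reports the sub-clusters as communities;
coarser planted structure is only restored when the sub-cluster signal is
weak enough for the algorithms to fragment it inconsistently.

**NMF on signed data.** Log-scale expression is signed; NMF requires
non-negativity. The default shifts the whole matrix by its global minimum
(preserves gene count); `posneg` mode splits each gene into positive and
negative parts (doubling rows), the standard alternative. Factorization
minimizes the Frobenius reconstruction error with Lee–Seung multiplicative
updates, one random initialization per resample (the ensemble supplies
stochastic replication), iteration cap 500, relative tolerance 1e−5.
Samples are assigned to the argmax factor of `H`, ties to the lowest index.

**k-means engine.** Subsample runs use the Hartigan–Wong algorithm
(`stats::kmeans`) with 10 restarts from distinct sampled centers, keeping
the restart with the lowest within-cluster sum of squares; Hartigan–Wong
never returns empty clusters, so no reseeding step is needed.

**Log-rank statistic.** `logrank_test()` delegates to
`survival::survdiff()`, i.e. the Mantel–Haenszel statistic with the full
covariance matrix — the standard implementation in this field. For two
groups it coincides with the hand-tallied `(O−E)²/V` form used as the
oracle in the tests.

**Shrunken centroids.** The full nearest-shrunken-centroid construction is
implemented (`d` standardized with pooled within-class SD plus the median
offset `s0`, `m_k = sqrt(1/n_k − 1/n)`, soft-thresholding by Δ), but
assignment uses Pearson correlation with the centroids rather than the
discriminant score, and Δ defaults to 0 because correlation assignment does
not require shrinkage; cross-validated Δ selection is available behind a
flag.

**Reproducibility.** A single master seed spawns independent named streams
(per-(algorithm, k) subsampling, label propagation per mode, permutation
test, survival simulation), so enabling or disabling one stage never
perturbs another, and rerunning a configuration reproduces every output
table byte for byte. The run manifest records all parameters and the seed.

## The synthetic cohort generator

`planted_design()` / `generate_expression()` emulate a desk-scale
expression cohort: Gaussian background noise (SD 1), top-level communities
with disjoint marker blocks shifted by `effect_size` noise-SDs in their
samples, optional nested sub-clusters with their own marker blocks, and
per-community exponential survival with exponential censoring. Defaults:
120 samples, 2000 genes, 3 communities × 2 sub-clusters, 100-gene marker
blocks (a typical published-signature size), shifts of 6 and 3 noise-SDs,
hazards geometrically spaced (0.05 × 3^(c−1) per study-time unit) with
censoring rate 0.05 — i.e. communities whose prognosis differs by a hazard
ratio of 3 per step and whose censoring fraction ranges from roughly half
to a tenth, plausible for metastasis-free follow-up.

What the generator does *not* emulate: probe/batch effects, heavy-tailed
or correlated noise, unbalanced community sizes, missingness. Passing
recovery tests on planted data therefore demonstrates correctness of the
machinery, not performance on real cohorts, where separation is far weaker
and the choice of *k* is genuinely subjective.

A cautionary property the test suite documents: on a *null* design (no
planted structure), consensus scores alone can look excellent — consensus
HC chains into near-singleton splits with high consensus silhouette. The
`min_cluster_size` column of the metrics table exposes this, and the
community silhouette computed on the expression distance (near 0 on null
data) is the honest diagnostic; the package's selection step uses the
latter.

## Numerical choices and degenerate inputs

* Consensus entries for sample pairs never co-sampled (possible at small
  n) are set to 0 with a warning rather than imputed.
* An all-equal consensus matrix cannot be cut into clusters and raises an
  error naming the (algorithm, k); a zero-variance distance vector makes
  the cophenetic coefficient undefined (`NA`), and such runs are never
  auto-selected.
* Silhouettes follow the standard convention that singleton clusters score
  0; a single-community reconciliation receives a sentinel (`NA`) score
  and cannot win selection.
* Duplicate gene identifiers keep the highest-SD row (consistent with the
  variance filter); rows with any missing or non-numeric value are dropped
  and counted — imputation is out of scope.
* Hypergeometric tests are exact (`phyper` upper tail); the global
  association test is a seeded Monte-Carlo chi-square (100 000 permutations
  by default), the practical stand-in for an r×c Fisher exact test, and is
  itself exact-in-the-limit rather than asymptotic.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the generator's default scale
(120 × 2000, 50 resamplings) once, and otherwise uses compact designs
(16–60 samples, 30–160 genes, 5–20 resamplings) chosen so that every
oracle comparison — exhaustive-merge linkage, brute-force k-means
partitions, hypergeometric enumeration up to N = 12, hand-tallied log-rank
— remains tractable and exact. Stochastic guarantees (log-rank power at
hazard ratio 3, null calibration, classifier recovery at noise
SD = 0.25 × contrast) use 100–500 seeded replicates.

## Known limitations

* Only Euclidean distance drives the clustering itself (the original
  tool's convention); correlation distance is available only for the
  community silhouette.
* The automatic *k* rule cannot reproduce judgment calls made from
  consensus-matrix inspection; explicit *k* is the intended mode for real
  cohorts.
* Gene matching across cohorts is by exact identifier; no aliasing or
  platform mapping.
* No Cox modeling, competing risks, or gene-set enrichment — survival
  output is the product-limit curve plus the log-rank test, and
  enrichment is against user-supplied sample labels only.
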