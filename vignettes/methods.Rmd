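---
title: "Methods: clustering fingerprint libraries and judging the result"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering fingerprint libraries and judging the result}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`molclust` implements a benchmarking protocol for clustering a small-molecule
library represented as binary Morgan fingerprints: compute pairwise Tanimoto
similarities, optionally remove nearest-neighbour outliers, cluster with three
different algorithms, and score every clustering with three internal validity
indices plus an average inter/intra-cluster similarity matrix. This vignette
explains the models and conventions behind each step, the choices we made
where the protocol leaves room, and what the synthetic-data validation does
and does not establish.

## Representation and similarity

Molecules are 0/1 bit vectors of length L (default 1024), each bit recording
the presence of a hashed circular substructure (Morgan radius 2 by default,
the ECFP4-equivalent setting). Hashing is delegated to the RDKit toolkit via
the system `python`; the package itself never interprets chemistry beyond the
bit matrix, so any binary fingerprint table can be supplied directly.

Similarity of two fingerprints is the Tanimoto coefficient
$T(A,B) = |A \cap B| / |A \cup B|$; distances are $1 - T$. Conventions:

* **All-zero fingerprints.** $T(\emptyset, \emptyset)$ is defined as 0, not
  1: an empty fingerprint shares no substructure with anything, itself
  included. This case is unreachable for parseable molecules but matters for
  synthetic inputs.
* **Blocking.** `tanimoto_distance()` and `nearest_neighbor_profile()` work
  in row blocks (default 256 rows) against the full bit matrix, so peak
  additional memory is O(block × n). The nearest-neighbour profile never
  materialises the condensed matrix at all — for a library of n molecules it
  keeps only the n running maxima, which is what makes the profile usable
  when the pair count runs into the billions (50,555 molecules already mean
  1.28 × 10⁹ pairs).
* **Ties.** Nearest-neighbour ties are broken towards the lowest molecule
  index, making every profile deterministic.

Distances are stored as a base-R `dist` object (64-bit doubles) in the
standard condensed lower-triangle order.

## Outlier filtering

A molecule is an *outlier at cutoff c* when its nearest-neighbour similarity
is ≤ c: at that similarity level it is different from every other molecule,
and no clustering method can place it meaningfully. The filter is a single
pass over the full-set profile; similarities are deliberately **not**
recomputed among retained molecules after removal, so a molecule whose only
close neighbour was removed stays retained. Re-running the filter on the
retained set can therefore flag additional molecules; this is documented
behaviour, not idempotence.

`scan_outlier_cutoffs()` reproduces the cutoff-selection experiment: for each
cutoff it filters, re-clusters the retained molecules with a baseline Ward
clustering (default linkage cutoff 3), and reports the three indices. Cutoffs
that leave fewer than two molecules or a single cluster yield `NA` metrics —
sentinels, never fabricated numbers.

`gap_cutoff()` picks a cutoff from a bimodal nearest-neighbour similarity
distribution as the midpoint of the widest gap between consecutive sorted
values. This is deterministic and works when an isolated low-similarity mode
exists (the planted-outlier setting); on unimodal distributions it returns an
arbitrary in-distribution midpoint and should not be used blindly.

## The three clustering routes

**Ward hierarchical.** Implemented directly from the Lance–Williams
recurrence on squared distances: after merging clusters $i, j$,
$d^2(ij,k) = \frac{(n_i+n_k)\,d^2(i,k) + (n_j+n_k)\,d^2(j,k) - n_k\,d^2(i,j)}
{n_i+n_j+n_k}$. Two singletons merge at their input distance, so heights live
on the scale of the supplied distances; heights are non-decreasing (Ward is
reducible), which every run asserts. The greedy minimum search breaks ties
towards the lowest pair index. This construction reproduces, merge for merge,
the standard "Ward on a precomputed distance matrix" tree (`hclust`'s
`ward.D2`), which the tests use as an independent cross-check. Trees are cut
either at a height (cophenetic criterion: all merges with height ≤ cutoff are
applied, so smaller cutoffs give more clusters) or into exactly k groups.

**Taylor–Butina.** Exclusion-sphere clustering at a similarity cutoff:
molecule j is a neighbour of i when $T(i,j) \ge$ cutoff. Iteratively, the
unassigned molecule with the most *unassigned* neighbours becomes a centroid
and absorbs its unassigned neighbours; leftovers are singletons, including
"false singletons" whose neighbours were attracted by a better centroid.
Tie-breaks go to the lowest molecule index. Note the direction this implies:
*lowering* the similarity cutoff widens the spheres and can only coarsen the
partition, so the cluster count is non-increasing as the cutoff is relaxed.
(Toolkits that parameterise the same algorithm by a *distance* cutoff show
the numerically opposite trend in their tables; the semantics here follow the
similarity definition.)

**UMAP + agglomerative.** Fingerprints are embedded in 2-D by UMAP under the
Jaccard metric and the embedding is Ward-agglomerated (reusing the same
linkage code on Euclidean distances) into a requested number of clusters. The
embedding optimiser is an external component (`umap-learn`), deliberately not
re-implemented; the package fixes its random state (default 42) and treats
"same seed + same input ⇒ same embedding" as a reproducibility contract on a
fixed environment. Batched helpers run many embeddings per interpreter start,
since interpreter + JIT start-up dominates small embeddings.

## Validity indices

All three indices are implemented from their definitions and checked against
naive-loop transcriptions to 10⁻⁹ on random instances:

* **Silhouette**: $a_i$ = mean distance to own cluster (excluding self),
  $b_i$ = smallest mean distance to another cluster,
  $SC(i) = (b_i - a_i)/\max(a_i, b_i)$; the score is the mean over molecules.
  Singleton clusters contribute $SC(i) = 0$ (the usual convention; $a_i$ is
  undefined there). Accepts either a feature matrix (Euclidean geometry) or a
  precomputed `dist`.
* **Calinski–Harabasz**: trace ratio of between- to within-cluster scatter
  times $(n-k)/(k-1)$. The decomposition satisfies
  $\mathrm{tr}\,W_k + \mathrm{tr}\,B_k = $ total scatter about the grand
  centroid (asserted to 10⁻⁹). Zero within-cluster scatter yields an `Inf`
  sentinel with a warning.
* **Davies–Bouldin**: mean over clusters of the worst
  $(s_i+s_j)/d_{ij}$ ratio. Coincident centroids with non-zero scatter yield
  `Inf`; two collapsed clusters at the same point give ratio 0.

Degenerate clusterings (k = 1) are validation errors for the index functions
and `NA` rows in `quality_report()`.

**Which feature space?** Variance-based indices need a vector space, and the
protocol never pins one down per method. Our convention: fingerprint-space
clusterings (Ward, Butina) are scored on the binary bit matrix under
Euclidean geometry; embedding-based clusterings are scored on the embedding
coordinates. Both spaces are available to callers, so the choice can be
overridden by passing the matrix you prefer to `quality_report()`. Absolute
index values are only comparable within one feature space — this is why
embedding-route scores are orders of magnitude larger than fingerprint-route
scores on the same data.

**Average similarity matrix.** Entry (p, q) is the mean Tanimoto similarity
over all cross pairs of clusters p and q; the diagonal averages over
unordered pairs of *distinct* within-cluster molecules (self-pairs excluded)
and is `NA` for singletons. A clustering is structurally convincing when
every defined diagonal entry exceeds the off-diagonal entries in its row;
this diagonal-dominance signature is asserted on planted data in the tests.
Cluster-size summaries report mean, sample SD, min/max and the
10/17/20/25/50/75 percentiles with linear interpolation (`quantile` type 7,
matching the benchmark's software stack).

## Hyperparameter tuning

The two-step procedure freezes the embedding before searching k. Step one
grids `(n_neighbors, min_dist)` at fixed k; each combination is scored by the
three indices on its own embedding, earns one "win" per metric it is best at
(max silhouette, max CH, min DB), and the winner takes the most wins —
majority-of-metrics, with ties broken towards smaller `n_neighbors`, then
smaller `min_dist`. Step two builds one agglomerative tree on the frozen
feature space and cuts it at every k in range, scoring either *distortion*
(sum of squared distances to the assigned cluster centroid; non-increasing in
k, asserted) or mean silhouette.

**Knee detection** follows a Kneedle-style rule with sensitivity S = 1: both
axes are rescaled to the unit square, the decreasing distortion curve is
flipped, and the knee is the k maximising the flipped curve minus the
diagonal; when that maximum falls below S times the mean x-step, the curve
has no discernible inflection and `NA` ("elbow unclear") is returned — flat
and exactly linear curves have no elbow, and the rule is invariant to
positive rescaling of the scores. For silhouette curves the selected k is
simply the argmax. One boundary limitation is inherent to the rescaling: the
smallest k in the scanned range is pinned to difference zero, so a knee *at*
the lower boundary (e.g. two planted clusters scanned from k = 2) cannot be
detected — the decisive drop from k−1 lies outside the scan. Interior knees
(e.g. seven planted clusters scanned over 2–15) are detected reliably, which
is the regime the protocol actually uses.

## The synthetic generator

`synthetic_spec()` plants K centroid fingerprints (each bit on with
probability `density`, default 0.05 ≈ 51 bits of 1024) and derives members by
bit-flip noise: an on-bit survives with probability 1 − ε_off, an off-bit
turns on with probability ε_on. Outliers are independent random fingerprints
with no relation to any centroid. Everything is driven by one seeded stream,
so a spec is a complete, reproducible description of a data set. ε may vary
per cluster to emulate analogue series of different tightness.

The `nci60_like_spec()` preset was calibrated once by simulation and frozen:
8 clusters (4 tight at ε_off = 0.05, 4 loose at ε_off = 0.20, ε_on = 0.008,
40 members each) plus 50% injected outliers. This reproduces the similarity
profile of a heterogeneous screening panel: nearest-neighbour similarity
median near 0.6 before filtering and near 0.7 after filtering at cutoff 0.5,
with roughly a third of molecules removed. What the generator does *not*
emulate: correlated bit patterns from shared scaffolds (bits flip
independently), activity cliffs, size-dependent bit densities, or the heavy
right tail of real cluster-size distributions. Passing the planted-recovery
tests therefore shows the algorithms are implemented correctly and behave as
designed on separable data — it does not show that any real library is this
separable; on the real panel the published indices indicate weak structure
in fingerprint space.

## Problem sizes and determinism

The test and acceptance workloads use libraries of a few hundred molecules
(e.g. 4 clusters × 100 members, 1024 bits) — large enough for stable ARI,
sensitivity and knee estimates, small enough that every suite re-runs in
minutes on one CPU. All stochastic steps take explicit seeds; the only
component whose bit-exact output may vary across *different* numerical
environments is the UMAP embedding, which is why its contract is stated as
determinism on a fixed environment.

## Known limitations

* Cluster labels use R's 1..k convention (first-appearance order).
* The Butina implementation recomputes neighbour counts against unassigned
  molecules each iteration (as specified); extremely large neighbourhoods
  make this O(n²) per pass in the worst case.
* `gap_cutoff()` assumes a genuinely bimodal nearest-neighbour distribution.
* The outlier filter is one-shot by design; iterative refiltering changes
  the retained set and is intentionally not performed.
* Published absolute index values for the real panel depend on an unstated
  feature-space choice and on the embedding seed, and are reproducible only
  up to those ambiguities plus access to the original molecule table; the
  package therefore validates against arithmetic identities and planted
  ground truth instead.
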