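---
title: "Fusing and filtering structural brain networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing and filtering structural brain networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectofuse)
library(dplyr)
```

## The problem

Tractography gives many defensible ways to weight the connection between two
gray-matter regions: the number of interconnecting streamlines, their density
corrected for region size, their average length, the tract's volume, the mean
fractional anisotropy or diffusivity along the bundle, or simply the Euclidean
distance between region centroids. Each choice produces a different structural
brain network (SBN) from the same scan, and downstream graph statistics can
disagree across choices. `connectofuse` implements a fusion strategy: compare
the nine weighted networks of a scan with a graph diffusion distance, convert
the comparison into convex combination weights, fuse the networks into one
integrated weighted SBN, and then topologically filter that fusion by
accumulating orthogonal minimal spanning trees up to the peak of global cost
efficiency. The package also ships the evaluation stack for such a method —
test-retest reliability (ICC), rank-sum comparisons, scan fingerprinting with
a k-NN classifier over diffusion distances, a quality-of-clustering index, MDS
embeddings, and lesion-based node weighting — plus a synthetic cohort
generator so the whole pipeline can be exercised end to end without MRI data.

## The nine edge weightings

From a tract table (one row per region pair per bundle, with streamline count,
mean length, white-matter length, volume, and tract-averaged FA/MD/RD) and the
ROI geometry (centroids in mm, gray-matter voxel counts), `build_nws()`
produces nine symmetric zero-diagonal matrices: `NSTR` (summed streamline
count), `PSTR` (`NSTR` over the whole-brain total, so its upper triangle sums
to one), `SD` (streamline density corrected for region size,
$w_{ij} = \tfrac{2}{g_i + g_j}\,|S_{ij}|$ with $g$ the voxel counts), `TV`
(summed tract volume), `ATL`, `FA`, `MD`, `RD` (streamline-count-weighted
means of the per-record metric), and `ED` (centroid Euclidean distances, dense
by construction and computed in native space). Where several bundles connect
one pair, the tensor metrics are aggregated by count-weighted averaging; the
aggregation rule is a package decision — the count weighting reflects how much
each bundle contributes to the connection. MD and RD are used as-is, with no
inversion into a "connection strength" direction.

Records can first be filtered by minimum contiguous white-matter length
(`length_filter()`); the conventional sweep is 0 to 6.0 mm in 0.5 mm steps
(`threshold_grid()`, 13 thresholds).

## Graph diffusion distance

For a weighted network $W$ with Laplacian $L = D - W$, heat diffusion
$\dot u = -L u$ has the kernel $\exp(-tL)$, whose columns are the diffusion
patterns seeded at each node. The distance between two networks is

$$d_{gdd}(W_1, W_2) = \max_{t>0}\; \lVert \exp(-tL_1) - \exp(-tL_2) \rVert_F^2 .$$

Both $t \to 0$ (all kernels approach the identity) and $t \to \infty$ (kernels
approach per-component projectors) shrink the difference, so an interior
maximum exists whenever the networks differ and share component structure.
Numerical choices:

* **Search.** $d(t)$ is evaluated on a 100-point logarithmic grid spanning
  $[10^{-3}, 10^{3}] / \lambda_{\max}(L_1 + L_2)$, then refined by bounded
  scalar maximisation around the grid argmax. The spectral-radius scaling
  makes the grid invariant to the overall weight scale.
* **Computation.** With spectra $L_k = V_k \Lambda_k V_k'$ computed once per
  network, $d(t) = \sum_i e^{-2t\lambda^{(1)}_i} + \sum_j e^{-2t\lambda^{(2)}_j}
  - 2\, a(t)' (V_1'V_2)^{\circ 2}\, b(t)$ with $a, b$ the eigenvalue
  exponentials, so a pairwise dissimilarity matrix costs one eigendecomposition
  per network and one $n \times n$ product per pair, with each grid point
  $O(n^2)$. This is an exact algebraic rewrite, not an approximation.
* **Normalisation.** The nine weightings carry incommensurate units (counts,
  mm, mm³, unitless), and unnormalised kernels are dominated by scale. The
  default `normalization = "max"` divides each matrix by its largest entry
  before comparison; `"strength"` (divide by total weight) and `"none"` are
  available and every serialised output records the mode. One consequence
  worth knowing: `PSTR` is a global rescaling of `NSTR`, so their
  max-normalised distance is exactly zero.
* Eigenvalues are clipped to zero from below at $10^{-10}$; disconnected
  graphs are allowed (the kernel stays well defined) and get no special
  casing.

## Fusion into an integrated network

Per scan, the pairwise dissimilarity matrix of the nine (prescaled) weightings
is summed across rows and normalised to total one (`integration_weights()`),
and the fused network is the weighted sum of the max-normalised matrices
(`integrate_nws()`). Row-sum weighting gives *more* weight to a strategy that
is more dissimilar from the rest; read literally this emphasises unique
topological information, and an `"inverse"` mode is exposed for the opposite
convention but is not the default. If every pairwise distance is numerically
zero (identical inputs) the weights are undefined; the implementation falls
back to uniform weights with a warning. Because the default prescaling maps
every weighting into $[0, 1]$, the fusion is a convex combination: each fused
entry lies between the element-wise minimum and maximum of the prescaled
inputs, and permuting the stack permutes the weights without changing the
result. `triad_integration()` applies the identical algorithm to the tensor
(FA, MD, RD), geometry (ATL, ED, SD) and streamline (TV, NSTR, PSTR) triads.

## Topological filtering by orthogonal minimal spanning trees

`omst_filter()` maps weights to distances by $1/w$ (strongest edge =
shortest), extracts successive edge-disjoint minimum spanning forests with
Kruskal's algorithm (deterministic tie-break by distance, then edge index; the
round loop runs in C++), and evaluates each cumulative union — carrying the
*original* weights — by

$$J = GE - \text{Cost},$$

where $GE$ is the weighted global efficiency of the selected subgraph and
Cost is the selected fraction of the full network's total weight. The union
maximising $J$ (ties resolved toward fewer rounds) is the filtered network.
Later rounds may legitimately return forests once earlier selections
disconnect the residual graph. Because $GE$ of a growing edge set can never
exceed the full network's efficiency while Cost increases strictly, the
search can stop as soon as $GE_{\text{full}} - \text{Cost}$ drops below the
best $J$ seen — an exact bound, so the reported peak is the global one;
`prune = FALSE` forces the exhaustive curve. $GE$ inside $J$ is computed on
the weighted selected subgraph (not a binarised one), consistent with the
original-weights convention used everywhere else.

## Network metrics

All path-based metrics share the $1/w$ distance convention: global efficiency
(mean inverse shortest-path length over ordered pairs; unreachable pairs
contribute zero), local efficiency (global efficiency of each node's
neighbour-induced subgraph; nodes with fewer than two neighbours score zero),
characteristic path length, eccentricity, radius and diameter (computed on
the largest connected component with a warning when the network is
disconnected — filtered networks are connected by construction since round
one is a spanning tree), and mean strength. The network-level eccentricity is
reported as the mean of node eccentricities; radius and diameter are its
minimum and maximum.

## Reliability and discriminability

* **ICC.** `icc()` implements the single-rater Shrout–Fleiss forms from
  explicit sums of squares; the default is one-way random ICC(1,1), treating
  repeat scans as indistinguishable sessions — the package's reading of a
  test-retest design without session structure; ICC(2,1) and ICC(3,1) are
  selectable and the form is carried in the output.
* **Rank-sum.** `wilcoxon_ranksum()` enumerates all rank assignments exactly
  (midranks for ties) when the combined sample is at most 12, and otherwise
  uses the tie-corrected normal approximation with continuity correction.
* **Fingerprinting.** `knn_recognition()` runs leave-one-out k-NN (default
  k = 4) on a diffusion-distance matrix across all scans, with deterministic
  tie-breaks (majority label, then smaller summed distance, then smaller
  subject index).
* **QCI.** The quality-of-clustering index is the equalised ratio of mean
  between-subject to mean within-subject distance, with the
  $\tfrac{scans(scans-1)/2}{scans^2}$ prefactor that makes a constant
  distance matrix score exactly one. The numerator averages over *all*
  $scans^2$ scan pairings of a subject pair while the denominator uses only
  the $scans(scans-1)/2$ within-subject pairs; the asymmetric summation
  bounds are kept exactly as defined because that is what the
  constant-matrix property validates. QCI is invariant to rescaling of the
  distance matrix.
* **Embedding.** `mds_embed()` is classical double-centering MDS
  (`stats::cmdscale`), zero-padding coordinates when the spectrum supports
  fewer axes than requested.

## Lesion-based node weights

`node_attack()` implements three per-node schemes: zeroing the strongest half
of a node's incident edges (ranked by weight, deterministic index tie-break;
"half" rounds up on odd degrees), halving all of them, or both combined.
`node_lesion_weights()` turns the per-node diffusion distances between
original and attacked networks into a weight vector summing to one;
`cluster_attack()` restricts a scheme to within/between edge classes of a
rich-club or modularity partition. Two under-specified constructions are
package decisions, both configurable: hubs are nodes whose strength exceeds
mean + 1 SD, rich-club hubs are hubs whose within-hub strength exceeds the
median within-hub strength of hubs; and modularity uses greedy agglomerative
maximisation on the weights. The lesion comparison defaults to
`normalization = "none"` because an attacked network lives on the same scale
as its original — max-rescaling would partially undo the attack.

A caution discovered while validating: when an attack *disconnects* the
graph (e.g. zeroing a lone bridge), the diffusion distance is dominated by
the change in component structure — the $t\to\infty$ kernels differ by a full
projector — so bridge lesions can outweigh much larger within-module lesions.
That is faithful to the diffusion geometry, not an artifact.

## The synthetic cohort generator

The generator emulates a test-retest tractography design (default: 5 subjects
× 5 scans × 90 ROIs, the classic small reliability cohort) without claiming
anatomical realism. Subject level: connection means decay with centroid
distance ($e^{-d/\lambda}$, $\lambda$ = 40 mm), are boosted within a
subject-specific random module partition (6 modules, boost ×2 by default),
and carry a stable per-edge log-normal fingerprint (sd 0.4). Scan level:
streamline counts are drawn from a negative binomial (size 8) around the
subject mean with a multiplicative log-normal drift (sd 0.1) — counting
noise, so weak connections flip in and out between repeat scans exactly as
real tractography counts do, which is the instability topological filtering
exists to remove. Setting the scan-noise scale to zero is the degenerate
noise-free case with deterministic counts, a property the tests rely on.
FA/MD/RD are subject-level truncated Gaussians with small additive scan
noise; `wm_length_mm` is the
tract length minus a positive offset with a small Beta-distributed retained
fraction, so a 0–6 mm threshold sweep removes a graded share of records.
Centroids are uniform in a brain-sized box and voxel counts log-normal
(median ≈ 1800).

What the generator does *not* emulate: spatially structured tractography
biases (length-dependent seeding, gyral bias), hemispheric symmetry, true
anatomical module layouts, or any DWI signal model. Passing end-to-end tests
therefore demonstrates that the method stack behaves as specified on
distance-decaying, modular, fingerprinted networks — not that any particular
reliability level would be attained on real scans.

## Problem sizes and empirical behaviour

The test suite exercises the full pipeline at the design scale (5 × 5 × 90)
at two operating points, skipping the (expensive, unneeded) node-level
metric tables via `cohort_pipeline(metrics = FALSE)`:

* **Low noise** (scan-noise 0.02, near-Poisson counts): the filtered fusion
  assigns every scan to the right subject (k = 4, leave-one-out accuracy
  1.0). This is the fingerprinting regime — within-subject distances are
  tiny, so identification is essentially perfect.
* **Default (realistic counting) noise**: across 20 replicate cohorts the
  filtered network's quality-of-clustering index beats the unfiltered one in
  every replicate (unfiltered ≈ 1.0–1.4, filtered ≈ 1.4–1.5). The two
  regimes are deliberately distinct: at near-zero noise there are no
  unstable weak edges for the filter to remove, so a systematic QCI gain
  from filtering only appears — and is only claimed — where scan noise
  exists. Smaller parcellations (≤ 40 ROIs) also weaken the contrast, since
  few strongly connected regions leave the filter little to prune.

## Known limitations

* Diffusion distances require equal node counts; there is no node matching.
* The OMST curve is defined on cumulative unions of whole rounds; the
  selection never splits a round.
* ICC assumes a complete subjects × scans grid; missing cells are an error
  rather than being imputed.
* The `BIN` (binary) weighting sometimes discussed alongside these nine is
  not implemented; the nine-strategy set is the package's scope.
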