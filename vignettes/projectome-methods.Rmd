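---
title: "Single-neuron projectome and morphometry methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-neuron projectome and morphometry methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projectomer)
```

`projectomer` quantifies long-range axonal projections and dendritic
morphology of completely reconstructed single neurons. The input is the
field's standard trio: SWC skeletons (one file per cell, nodes typed as
soma/axon/basal/apical with coordinates in micrometres), a 3D integer label
volume standing in for an annotated reference atlas, and a cell metadata
table. Every downstream statistic — connectome matrices, axon-cloud overlap,
topography, hierarchy, morphometric classification — is computed from these
three inputs, so the whole pipeline can be exercised end to end on synthetic
populations with planted ground truth.

## Morphology representation and arbor decomposition

A neuron is a rooted tree; segments are straight parent-to-child links.
Atlas voxels are half-open boxes (`[origin + i*voxel, origin + (i+1)*voxel)`,
0-based indices) and the hemisphere of a point is decided deterministically
against a midline plane. Three conventions matter downstream:

* **Segment-to-region assignment** is by the region of the child node, with
  no sub-segment clipping. This is simple, deterministic and conserves cable
  exactly: summed arbor lengths equal each cell's total axonal length to
  1e-6 um for any atlas partition (a property the test suite asserts on
  every generated population). The cost is a worst-case error of one
  inter-node spacing at each region crossing, which is why the synthetic
  generator emits trunk nodes every ~20-30 um.
* **Branch order within an arbor** restarts at the arbor's entry nodes (the
  first nodes inside the region), not at the soma. The target filter below
  needs a "second-order bifurcation", which we read as a branch point
  downstream of another branch point *within the same arbor* — equivalently,
  a maximum within-arbor branch order of at least 2. Counting from the soma
  instead would let a cell's global branching history qualify tiny local
  sprays, which is exactly what the criterion exists to prevent.
* **Resampling**: centroids and scatter statistics are computed after
  interpolating every segment at a uniform step (default 1 um for
  centroids), so node density does not bias spatial statistics; as the step
  shrinks the centroid converges to the closed-form length-weighted
  segment-midpoint centroid, and the tests bound the difference by the step.

## Projection target calling

An arborization in a region counts as a projection target when

* its axonal length exceeds 1000 um and it contains at least one terminal
  node, or
* its length is between 20 and 1000 um (inclusive on both ends; "exceeding
  1000" claims the open interval above) and it contains at least one
  terminal *and* one second-order bifurcation.

Long terminal-free arbors are passing fibers; short unbranched pieces are
tracing spikes or fibers clipping a corner of the region. Both are excluded.
`TargProb` for a (cell type, source area) group is the percentage of its
cells with a passing arbor in a (region, hemisphere) column; `TargStren` is
the mean arbor length over *passing* cells only (the per-cell "AxL/C" unit).
Averaging over all cells instead would conflate probability and strength;
it remains available as a configuration choice. Cells without any arbor in
a region simply contribute to the denominator.

## Axon-cloud overlap

For two clouds of grid-interpolated axon points (every Cartesian grid cell
crossed by a segment contributes a point, via exact voxel traversal), the
separability is the ratio of scatter-matrix traces

$$S = \frac{\mathrm{tr}(S_B)}{\mathrm{tr}(S_W)}, \qquad
S_B = \sum_{i=1}^{c} n_i (m_i - \bar m)(m_i - \bar m)^T, \qquad
S_W = \sum_{i=1}^{c} \sum_{j=1}^{n_i} (x_{ij} - m_i)(x_{ij} - m_i)^T,$$

with $c = 2$ classes, and the overlap is $O = \max(0, 1 - S)$: 1 for
coincident clouds, 0 once the between-class spread reaches the within-class
spread. Cloud sizes enter $S_B$ as written — no subsampling. $O$ is
symmetric and invariant under joint rigid motions, and the implementation is
checked against a brute-force double-loop trace computation to 1e-9. If
$\mathrm{tr}(S_W) = 0$ (degenerate point-mass clouds) the overlap is 1 when
the means coincide and 0 otherwise, flagged.

## Cloud volume by kernel density

Cloud volumes use a Gaussian product-kernel density evaluated on the atlas
voxel grid over the cloud's bounding box. The bandwidth (default 0.3) is
applied in per-axis standardized coordinates, because it is a unitless
smoothing parameter; a raw-micrometre bandwidth is available
(`standardize = FALSE`). The volume is the number of voxels with density at
or above 1% of the cloud's *own maximum* density, times the voxel volume —
the threshold is relative, which makes the estimate invariant to cloud size
and to the (unnormalized) density scale. Mean axon density is total axonal
length divided by that volume (um/um^3). Note a geometric consequence the
tests document: a relative threshold as low as 1% includes a kernel halo of
roughly 2.3 bandwidths beyond the cloud's support, while thresholding at
half maximum recovers the support of a uniformly filled solid almost
exactly.

## Topography

For one source area and one target region, let $S$ be the soma positions of
projecting cells and $C$ their paired arbor centroids. Both sets are
projected onto their own first principal axes (leading covariance
eigenvectors, the Hotelling transform) and the topography is the Spearman
rank correlation $\rho$ of the projections, with average ranks on ties;
cells that do not project are excluded from the pairing and reported as the
projecting fraction. $\rho = 1$ means somata and arborizations are arranged
in the same order along their dominant axes; negative $\rho$ means mirrored
order.

An eigenvector's sign is arbitrary, and an arbitrary sign flips $\rho$. We
fix it deterministically: the axis component of largest magnitude is made
positive (smallest index on ties, flagged). This is one consistent
convention, not a recovered property of any particular dataset. A second
caveat is structural: the method assumes each set's leading axis is the
topographic axis. When a cloud's variance is nearly isotropic the leading
eigenvector is unstable and $\rho$ degrades; the generator therefore plants
band-shaped projection fields (narrow mediolateral band, compact
per-cell arbors) so the assumption holds — as it does in elongated real
projection fields — and the tests demonstrate both the high-signal regime
(|rho| > 0.8 at small placement noise) and reliable sign recovery at
moderate noise.

## Hierarchy scores and FF/FB bias

The hierarchy score of region $j$ is
$\sum_{i \ne j} P_{ij} / \bar L_{ij}$, where $P_{ij}$ is the probability
(as a fraction) that a cell of source region $i$ targets $j$ and
$\bar L_{ij}$ is the mean targeting length, computed over passing cells for
consistency with `TargStren`. Normalizing by $\bar L$ counters the size
bias of large targets: what ranks a region highly is being targeted often
relative to the spatial extent of the clusters it receives. Regions never
targeted score 0, and a positive probability with a missing mean length is
an error rather than a silent drop.

For feedforward/feedback classification, each connection from source $j$ to
target $i$ contributes a hierarchy difference $\Delta h = h_i - h_j$ from an
externally supplied level table (planted by the generator here; in real use
these come from prior anatomical models). Connections are weighted uniformly
per passing (cell type, source, target) observation, not by strength. Each
cell type's $\Delta h$ distribution is compared with a variance-matched
Gaussian centred at zero: we draw 1000 seeded Gaussian reference samples
(mean 0, sd and size matched), run a two-sample Wilcoxon rank-sum test
against each, and report the median p-value — the reference sample size and
aggregation are deliberately explicit choices, and a one-sample signed-rank
mode is provided as an alternative. P-values are Benjamini-Hochberg adjusted
across cell types; FF requires adjusted p below 0.05 with positive mean,
FB the same with negative mean. A constant sample is degenerate: the
matched reference collapses to a point mass at zero, so a nonzero mean
forces the verdict. Calibration is tested empirically: type-I error at most
0.07 at nominal 0.05 over 500 symmetric-null replicates, and power above
0.9 for $\Delta h \sim N(0.5, 1)$ at $n = 100$. The rank-sum p-values in
this loop use a continuity-corrected normal approximation (exact at these
sample sizes to ~1e-10 against `wilcox.test`, as asserted in the tests),
which makes a thousand reference comparisons per distribution cheap.

## Morphometry

The nine-feature panel per compartment: height (extent along the declared
cortical-depth axis, including the attachment point), max Euclidean distance
from the soma, max along-tree pathway length from the soma, total pathway
efficiency, average bifurcation angle (degrees between daughter directions),
average segment length (cable length per unbranched run), and the numbers of
segments, bifurcations and tips. Two of these names circulate without a
fixed definition, so the package declares its own and documents them as
stand-ins: *height* is the depth-axis extent (rotation-sensitive by design,
translation-invariant), and *total pathway efficiency* is the mean over tips
of Euclidean-to-path-length ratio — 1 for perfectly straight paths, falling
with tortuosity. An extended 21-feature panel for clustering is
reconstructed as the nine apical features, their axonal analogues, plus
dendrite count and soma layer; its exact composition is configurable because
the original selection is not recoverable.

Features are min-max normalized (constant features dropped with a warning),
clustered with one-minus-Pearson distance and average linkage, and the
dendrogram is cut at the number of planted types. *Clustering accuracy* is
the fraction of correctly clustered cells after the best one-to-one
cluster-to-type assignment — computed exactly by exhaustive permutation for
up to 8 clusters (all uses here), greedily beyond; majority-label mapping is
the less conservative alternative. The random-forest classifier uses 500
trees and default depth on a stratified 80/20 split; hyperparameter search
is deliberately out of scope. On planted feature tables whose class means
are separated by at least 3 within-class standard deviations, both
clustering accuracy and test accuracy reach 0.9, the regime the acceptance
checks assert.

## The synthetic generator

`synth_atlas()` builds a block-partitioned label volume: cortical areas as
blocks along the anteroposterior axis, optionally split into layer slabs
along depth, mirrored into two hemispheres across the midline, with an
unlabeled white-matter gap above subcortical blocks. `generate_population()`
realizes cell-type specifications: somata in the source area; template
dendrites (tufted/untufted/inverted/horizontal/stellate at type-specific
scales); and, per planted target drawn from the profile, an axon trunk that
descends to the white-matter gap, travels there (so it crosses other
regions only as terminal-free passing fiber), ascends into the target and
forms a compact two-level branching arbor — four terminals, maximum
within-arbor branch order 2 — whose in-region length matches the planted
mean within a ~8% multiplicative draw. Topographic modes map the soma's
position (optionally mirrored) onto the arbor anchor with Gaussian noise
inside a narrow band. An optional straight fiber through a named area, with
its ending outside the volume, tests filter specificity. Same seed, same
bytes: populations are bit-reproducible.

What the generator emulates: cell-type-specific target sets, probabilities
and strengths; laminar placement; ipsi/contra ratios; topographic gradients;
a hierarchy driving targeting probability; passing fibers. What it does not:
realistic dendritic electrotonics, curved fascicle trajectories, soma
position errors from registration, reconstruction noise, or inter-animal
variability. Passing tests therefore demonstrate that the *estimators*
recover planted statistical structure at realistic scales — they do not
certify performance on real reconstructions.

Problem sizes used by the test suite were chosen as the smallest that leave
comfortable statistical margins: 200 cells/type for probability/strength
recovery (binomial SE ~3 points) and hierarchy recovery across 5 planted
levels; 50 cells/source for topographic sign recovery over 12 seeded
populations; 500 replicates for null calibration and 200 for power; 100
seeded instances for the overlap-oracle comparison.

## Numerical conventions and degenerate inputs

Boundary arbors of exactly 20 or 1000 um fall in the banded criterion.
Spearman uses average ranks on ties. Tied leading eigenvalues take the
first eigenvector, flagged. Zero-variance vectors in correlations return NA
with a degenerate flag rather than a value. All Monte Carlo procedures
(permutation p-values, Gaussian references, the generator) are seeded
explicitly, and reported p-values from permutations use the add-one
estimator (k+1)/(n+1).

## Workflow

The `analysis/` scripts run the full story on simulated cohorts:
`01_simulate.R` (population), `02_projectome.R` (arbors, filter,
connectome, laminar profile, hemispheric symmetry), `03_convergence.R`
(overlap matrices, KDE volumes, composition clustering), `04_topography.R`,
`05_hierarchy.R` (scores, correlates, FF/FB) and `06_morphometry.R`
(features, clustering, random forest), each writing tables under
`results/`.
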