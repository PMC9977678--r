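---
title: "Methods: segmentation-free co-localization analysis for molecule-resolved spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-free co-localization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatcoloc)
```

## The problem

Imaging-based spatial transcriptomics assays of the molecular-cartography
type report every detected RNA molecule with sub-micrometre 2D coordinates
for a panel of genes. A natural question in tissue immunology is whether two
cell types — say eosinophils (`SIGLEC8`) and CD4 T cells (`CD4`) in inflamed
colon — sit next to each other more often than chance would have it. The
obvious route, segmenting cells and assigning molecules to them, inherits
every weakness of nuclear segmentation in dense inflamed tissue.

`spatcoloc` implements both routes:

* a **segmentation-free** branch that treats spatial clusters of same-gene
  marker transcripts as cell proxies, connects nearby clusters into a
  neighbourhood graph, and scores cross-type proximity against a
  vertex-label permutation null;
* a **segmentation** branch that expands nuclear label masks, assigns
  molecules to the expanded segments and quantifies double-positive segment
  fractions;
* a **dual-channel spot** module for immunofluorescence co-expression
  (active vs basal eosinophils by nearest-spot distance) with a
  luminal-vs-basal crypt-third comparison;
* a **synthetic-data** module that generates marked point patterns with
  known ground truth, so every stage above is testable without any external
  data.

## The segmentation-free model

### Transcript clustering

For each marker gene, within each (slide, ROI), the pairwise Euclidean
distances of the molecule coordinates are clustered by **unweighted average
linkage** (UPGMA: the distance between two clusters is the mean over all
inter-cluster point pairs) and the dendrogram is cut at
`cut_height = 5` µm. Average linkage rather than single linkage prevents
chaining of stray molecules between neighbouring cells. A cluster of
`SIGLEC8` molecules then stands in for one eosinophil, its centroid for the
cell position.

Numerical conventions, chosen for bit-stable determinism:

* the cut is **boundary inclusive** — a merge at exactly 5 µm is realized;
* tied merges resolve to the lexicographically smallest pair of current
  cluster ids, a cluster's id being the smallest input index among its
  members;
* clustering never crosses gene or ROI boundaries;
* more than 50 000 molecules for one gene/ROI is refused with advice to
  tile: the distance matrix is quadratic and this implementation (Rcpp,
  nearest-partner caching over a full distance matrix) is meant for the
  per-ROI scale. Memory, not time, is the binding constraint from roughly
  20 000 points upward.

Average linkage is reducible, so merge heights are non-decreasing and
stopping at the first minimum above the cut is equivalent to cutting the
full tree.

### Neighbourhood graph and permutation test

Cluster centroids become typed vertices; an edge connects two clusters **no
further apart than** `graph_radius = 10` µm (inclusive). The fixed-radius
search uses a uniform grid index and is exact and uncapped; a diagnostic
warning reports vertices with more than `k_cap - 1 = 40` within-radius
neighbours, the regime in which a historical k-nearest-neighbour
implementation with k = 41 would have truncated the query.

For a type pair (A, B) the observed number of A–B edges is compared with an
empirical null obtained by uniformly permuting the **whole vertex label
multiset** (all marker types jointly) `m = 1000` times while the edge set
stays fixed. Both one-sided p-values use the add-one estimator

> p = (b + 1) / (m + 1),

where b counts permutations at least (resp. at most) as extreme as the
observed count, so p is never below 1/(m + 1) and never zero. The test
conditions on tissue composition and spatial structure: only the assignment
of types to positions is randomized.

A slide contributes a **sign**: +1 if the upper tail is significant at
`alpha = 0.05` (interaction), −1 if the lower tail is (avoidance), 0
otherwise; if both tails fall under alpha the smaller p decides. The
**proximity score** of a pair is the signed fraction of slides,

> score = (#slides with +1 − #slides with −1) / #testable slides,

in [−1, +1]. Slides where a pair is untestable (a type absent, or an
edgeless graph) are excluded from the denominator — scoring them 0 would
shrink scores for rare types for reasons unrelated to biology.

Design choices where the original description was open:

* "more extreme" is resolved as two one-sided tails, reported separately;
  the score's sign comes from whichever tail is significant;
* alpha = 0.05 is the conventional reading of "significant" and is
  configurable;
* no multiple-testing correction is applied across type pairs; raw per-pair
  p-values are reported;
* adjacency uses centroid-to-centroid distance (clusters are the graph's
  point objects); minimal inter-member distance is a noted alternative;
* clustering and testing are confined to ROIs because the reported
  statistics are per-image; per-(slide, pair) permutation seeds derive from
  the master seed, so parallel execution cannot change results.

### Neighbour expression

To ask whether reference cells adjacent to a partner type carry a different
molecular programme, reference clusters are split into
**partner-associated** (≥ 1 graph edge to a partner cluster, the inclusive
10 µm radius) and non-associated. Query-gene molecules — any gene in the
table, not only markers — are counted within a **strict** `< 10` µm of each
reference centroid; the two radii are deliberately separate configuration
fields because the published definitions differ in exactly this way. Per
ROI, the mean count per reference cluster is formed for each group, and the
per-ROI group means enter a two-sided **paired Wilcoxon signed-rank test**
across ROIs (ROIs, not patients, are the pairing unit).

The Wilcoxon test is exact by enumeration for up to 25 informative pairs:
zero differences are dropped, tied absolute differences get mid-ranks, and
the null distribution of the signed-rank statistic is built by convolving
the generating function over doubled mid-ranks (integers even with
mid-ranks). `stats::wilcox.test` switches to a normal approximation as soon
as ties or zeros appear, which small integer count differences produce
routinely — hence the in-package implementation; above 25 pairs a normal
approximation with tie-corrected variance and continuity correction takes
over. The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`, capped at
1 when w sits at the null median.

Counting is centroid-based; counting from every member molecule (union of
per-molecule discs) is a noted alternative that would weight large clusters
more heavily.

## The segmentation branch

Nuclear label rasters (one integer per nucleus, 0 background) are
**expanded** by `expand_distance_px = 10` px: every background pixel within
Euclidean distance ≤ 10 px (centre-to-centre) of a labelled pixel takes the
label of the nearest labelled pixel, equidistant ties going to the lower
label id. At the native `pixel_size = 0.138` µm/px this is the printed
1.38 µm reach. Molecules then map to the label of their containing pixel —
the point (x, y) µm falls in 0-based pixel (floor(y/s), floor(x/s)) with
origin at the raster's top-left corner — and segments with fewer than
`min_molecules = 3` molecules **or** fewer than `min_genes = 3` distinct
genes are flagged removed (kept in the table for audit; downstream
summaries use retained segments only).

The **double-positive fraction** for (gene_a, gene_b) is, among retained
segments with ≥ `min_count` molecules of gene_a, the share that also has
≥ `min_count` of gene_b. The positivity threshold is not standardized
anywhere; ≥ 1 molecule is the permissive default and the parameter is
exposed. Whether the denominator should include removed segments is equally
unstated; retained-only is used. With no gene_a-positive segment the
fraction is undefined and returned as `NA` with a classed warning — never
as 0.

## The dual-channel spot module

Green-channel spots (the cell marker, e.g. MBP for eosinophils) are
classified by the distance to their nearest red-channel spot (the activation
marker, e.g. PD-L1): **active** iff that distance is strictly below
`spot_threshold = 4` µm, otherwise basal. Distances are 3D when both
channels carry z, 2D otherwise, never mixed. The per-core
**active-to-basal ratio** is n_active / n_basal, undefined (flagged, not
infinite) when no basal spot exists. For crypt polarity, per-core y-ranges
mark the luminal (upper) and basal (lower) crypt thirds — an axis-range
stand-in for manually drawn regions — and the per-core (luminal − basal)
ratio differences enter a two-tailed paired Student's t-test with n − 1
degrees of freedom. Zero-variance nonzero differences are flagged
degenerate rather than producing an infinite t; identical patterns give
t = 0, p = 1.

## The synthetic world

`simulate_slide()` draws, per cell type, centres as a homogeneous Poisson
process (default `cell_density = 300` cells/mm² in a 300 × 300 µm field),
lets each cell emit Poisson(`transcripts_per_cell = 12`) molecules at
centre + isotropic Gaussian(`scatter_sigma = 1.0` µm) offsets clamped to
the field, and adds uniform background molecules
(`background_rate = 100` /mm², random marker gene, < 1% of molecules —
the low-background regime these assays advertise). Interactions act on
type-b centres: **colocalized** replaces a fraction ρ of them with a
randomly drawn type-a centre plus Gaussian jitter (default 2 µm);
**avoiding** redraws proposals closer than the hard-core distance to any
type-a centre (erroring out after 10⁴ rejections when the packing is
infeasible). All randomness flows from one master seed through a
counter-based per-slide split, so any slide is reproducible in isolation.

Why these defaults:

* `scatter_sigma = 1.0` µm keeps a cell's transcript cloud compact enough
  that one cell yields one cluster under the 5 µm cut (3σ ≈ a
  lymphocyte-sized soma radius). This is not cosmetic: at σ = 1.5 µm about
  9% of Poisson(12)-molecule cells already split into satellite clusters,
  and satellites sit within graph radius of their parent, creating
  within-type edges that break the label-exchangeability the permutation
  null assumes — the test then reports spurious *avoidance* between truly
  independent types. The method's premise (cluster ≈ cell) fails before its
  statistics do.
* `cell_density = 300` cells/mm²: a literature-scale density for one
  abundant immune subset in inflamed mucosa. Density also bounds a second
  intrinsic bias: same-type cells closer than the cut height **fuse** into
  one cluster while cross-type pairs at the same separation survive as
  edges, so observed cross-type counts sit slightly above the permutation
  null, increasingly so at higher densities. The type-I acceptance test
  (200 independent slides) passes in a window around this density; the
  fusion mechanism itself is a real property of segmentation-free
  clustering on real tissue and is worth knowing when interpreting
  weakly-positive scores at high densities.
* the avoidance demonstration uses its own world (150 cells/mm² in a
  600 × 600 µm field, σ = 3 µm): a 30 µm hard core cannot pack at the
  default density, and detecting avoidance needs within-type edge mass for
  the lower tail to resolve — here supplied deliberately by dispersed
  transcripts splitting cells into nearby satellite clusters.

`simulate_spot_sets()` builds the spot world to the classifier's
assumptions: green spots keep a minimum mutual separation of
`spot_threshold + pair_distance`, exactly `round(f · n_green)` of them get
a red partner at exactly `pair_distance` (< 4 µm), and decoy red spots are
rejected within the threshold of any green spot. Under this construction
nearest-distance classification recovers the true labels with zero errors
and the ratio equals f/(1 − f) — which is what the recovery acceptance test
asserts. `luminal_bias` places true-active spots into the luminal third
with the given probability.

What the generator does **not** emulate: optical point-spread functions,
z-stacks, transcript misidentification, segmentation errors in the label
rasters (nuclei are ideal disks), anisotropic or cell-shaped transcript
clouds, and density gradients across the field. A green test therefore
establishes correctness of the computations and calibration under the
stated point-process world — not robustness to the full messiness of real
tissue.

## Worked example

```{r example}
cfg <- run_config(marker_genes = c("CD4", "SIGLEC8"), rng_seed = 1)
specs <- list(cell_type_spec("Tcell", "CD4"), cell_type_spec("Eos", "SIGLEC8"))
ia <- interaction_spec("Tcell", "Eos", "colocalized", pairing_prob = 1)
sims <- simulate_slides(4, specs, list(ia), seed = 1)
tab <- transcript_table(do.call(rbind, lapply(sims, `[[`, "table")))
res <- run_proximity_analysis(tab, cfg)
res$scores
res$results[[1]]
```

## Degenerate inputs and guards

* permutation test: fewer than 2 vertices, no edge, or a single vertex type
  → classed error (`spatcoloc_degenerate`);
* proximity score: untestable (slide, pair) combinations excluded and
  logged; duplicated results for one (slide, pair) refused;
* Wilcoxon: all-zero differences → `NA` statistics with an `undefined`
  flag; paired t: zero-variance nonzero differences → degenerate flag;
* ratios with empty denominators → `NA` plus classed warning
  (`spatcoloc_undefined`), never 0, never infinity;
* out-of-bounds molecules in segment assignment are dropped and counted;
  conservation (assigned + unassigned + out-of-bounds = input) is tested;
* hard-core and decoy rejection sampling error out, with advice, when the
  requested geometry is infeasible.

## Known limitations

* The cluster-fusion and satellite-splitting biases described above are
  intrinsic to segmentation-free clustering: scores near the significance
  boundary at high cell density or large transcript scatter deserve
  scepticism, and the generator's defaults deliberately sit in the regime
  where the method's premise holds.
* The agglomeration holds a full distance matrix; per-ROI inputs beyond
  ~20 000 molecules per gene should be tiled.
* The permutation null is per-slide; no pooling or hierarchical model
  across slides is attempted beyond the signed fraction-of-slides score.
* Thirds annotations are y-axis ranges, not polygons; crypts running
  obliquely through a core need pre-rotated coordinates.
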