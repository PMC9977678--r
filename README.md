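# spatcoloc

Segmentation-free co-localization analysis for molecule-resolved spatial
transcriptomics, plus the segmentation-based and dual-channel
immunofluorescence quantifications that accompany it.

## Who this is for

Groups analysing imaging-based spatial transcriptomics
(molecular-cartography-style assays: one record per detected RNA molecule,
2D coordinates in µm, a marker-gene panel) who want to ask *do transcripts
of cell type A sit near transcripts of cell type B more (or less) often
than chance?* without trusting cell segmentation in dense tissue — the
motivating case being eosinophil–CD4 T cell proximity (`SIGLEC8`/`CD4`) in
inflamed human colon.

## The method

**Segmentation-free branch.** Per gene and per slide/ROI, molecules are
grouped by unweighted average-linkage hierarchical clustering of their
pairwise Euclidean distances with the dendrogram cut at h = 5 µm; each
cluster is a cell proxy. Cluster centroids become typed vertices of a
neighbourhood graph with an edge whenever two centroids are no further
apart than r = 10 µm. For a type pair the observed cross-type edge count
E_obs is compared against an empirical null built by uniformly permuting
the vertex-label multiset m = 1000 times with the edge set fixed; each tail
gets the add-one permutation p-value

    P = (b + 1) / (m + 1),

b = number of permutations at least (resp. at most) as extreme as E_obs.
A slide's sign is +1 / −1 / 0 by which tail clears α = 0.05, and the
**proximity score** of a pair across a study is

    score = (#slides with sign +1 − #slides with sign −1) / #testable slides  ∈ [−1, +1].

A companion comparison counts query-gene molecules strictly within 10 µm of
reference clusters that do vs do not have a partner-type neighbour, and
tests the per-ROI group means with an exact two-sided paired Wilcoxon
signed-rank test (ties mid-ranked, null by full enumeration up to 25
pairs).

**Segmentation branch.** Nuclear label rasters are expanded by 10 px
(1.38 µm at 0.138 µm/px, Euclidean, ties to the lower label), molecules are
assigned to the expanded segments, segments with < 3 molecules or < 3 genes
are removed, and double-positive fractions (e.g. share of SIGLEC8⁺ segments
also CD4⁺) are computed over retained segments.

**Spot branch.** Green-channel spots are *active* iff their nearest
red-channel spot lies strictly closer than 4 µm, else *basal*; per-core
active-to-basal ratios are compared between luminal and basal crypt thirds
with a two-tailed paired t-test.

**Synthetic data.** A first-class generator produces marked point patterns
(Poisson cell centres; per-cell Poisson transcript clouds; uniform
background; colocalized / independent / avoiding cross-type structure) and
paired spot sets with a tunable co-expression fraction — with full ground
truth, so every stage is testable offline. See the methods vignette
(`vignettes/segmentation-free-colocalization.Rmd`) for the model, parameter
rationale and known limitations.

## Worked example

```r
library(spatcoloc)

cfg   <- run_config(marker_genes = c("CD4", "SIGLEC8"), rng_seed = 1)
specs <- list(cell_type_spec("Tcell", "CD4"), cell_type_spec("Eos", "SIGLEC8"))
ia    <- interaction_spec("Tcell", "Eos", "colocalized", pairing_prob = 1)

sims <- simulate_slides(4, specs, list(ia), seed = 1)
tab  <- transcript_table(do.call(rbind, lapply(sims, `[[`, "table")))
res  <- run_proximity_analysis(tab, cfg)
res$scores
#>   gene_a  gene_b score n_slides n_pos n_neg
#> 1    CD4 SIGLEC8     1        4     4     0
res$results[[1]]
#> permutation_result CD4-SIGLEC8 (slide S1): observed 19, null mean 11.69,
#>   p_greater 0.000999, p_less 1, sign +1
```

Every simulated slide individually rejects the permutation null in the
upper tail (p = 1/1001, the minimum attainable at m = 1000), so the
CD4–SIGLEC8 score is +1: the engineered attraction is detected on 4 of 4
slides. The spot branch reads analogously:

```r
s   <- simulate_spot_sets(n_green = 200, coexpr_fraction = 0.4, seed = 2)
cls <- classify_spots(s$green, s$red, threshold = 4)
active_basal_ratio(cls)
#>   core_id n_active n_basal     ratio ratio_defined
#> 1      C1       80     120 0.6666667          TRUE
```

80/120 = 0.67 is exactly f/(1 − f) for f = 0.4 — the generator plants the
red partners below the threshold and keeps decoys beyond it, so the
classifier recovers the truth without error.

A thin command-line wrapper with subcommands `simulate`, `cluster`,
`proximity`, `segment-assign`, `neighbour-expr` and `spots` lives at
`inst/cli/spatcoloc.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analyses from scratch at the given seed — the
segmentation-free pipeline on a co-localized batch and an independent
control batch, the neighbour-expression comparison, the segmentation branch
on a rasterized slide, and the dual-channel spot quantification with the
crypt-thirds test — printing a one-line summary per stage and writing the
JSON report to `--out`.
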