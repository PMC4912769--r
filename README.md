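# micromorph

Automated morphometry and phenotypic clustering of microglia — the
resident macrophages of the central nervous system — from single-channel
(GFP-type) confocal image stacks.

Microglial morphology tracks microglial function: ramified cells with
small somata and branched process arbors dominate the healthy brain,
while activation shrinks the arbor down to the amoeboid form. This
package implements the full measurement chain needed to quantify that
continuum over thousands of cells:

1. **Imaging** — multi-page TIFF stacks are split into three axial
   sub-volumes (16 planes → 6/5/5) and reduced by maximum-intensity
   projection; tiles assemble into physically calibrated mosaics
   (default 0.19 µm/px).
2. **Segmentation** — somata by robust global thresholding + 2 µm
   morphological opening + half-maximum refinement; process networks by
   Guo–Hall thinning of the soma-subtracted foreground into a geometric
   skeleton graph with junction/endpoint nodes, polyline edges, and
   per-cell attribution (unattributed fragments are reported, never
   silently dropped).
3. **Morphometry** — per cell: soma and cytoplasm areas, roundness
   (4πA/P², chain-code perimeter), background-subtracted fluorescence,
   ramification counts by branch order, total process length, and the
   two derived indexes:
   * **complexity index** `CI = n_segments / n_primary` — mean branching
     complexity per primary process; `CI = 1` defines the amoeboid
     phenotype (no branch nodes);
   * **covered environment area** `CEA` — convex-hull area over the
     process extremities (µm²).
4. **Population filtering** — soma size window 10–500 µm², roundness
   ≥ 0.7, mosaic-edge removal, and merging of duplicate detections on
   adjacent sub-volumes.
5. **Phenotyping** — k-means (k = 4, k-means++/Lloyd, z-scored
   features) on (CI, CEA), and quadrant sub-populations SP1–SP4 cut at
   the control-group means.
6. **Statistics** — normality-gated t / exact Mann–Whitney two-group
   comparisons at the animal level, Kruskal–Wallis across regions, χ²
   on sub-population tables, Spearman correlations, and the two-sample
   sample-size calculator
   `n = ⌈2 (z₁₋α/₂ + z₁₋β)² σ² / (m̄_A − m̄_B)²⌉`.
7. **Cartography** — in-situ single-cell maps coloured by a (CI, CEA)
   gradient, cluster, or sub-population, with a machine-readable
   annotation table.

A synthetic-tissue generator (`generate_cell()`, `generate_tissue()`,
`generate_cohort()`) grows ramified/amoeboid cells with exact analytic
ground truth — counts per branch order, CI, CEA, areas — and renders
them into image stacks, so every stage above is validated against known
answers without any microscope data. See the methods vignette
(`vignettes/microglia-morphometry.Rmd`) for models, parameter meanings
and design rationale.

## Worked example

Simulate one calibrated tissue stack, quantify it, and filter:

```r
library(micromorph)

spec <- tissue_spec(width_px = 2600, height_px = 2600, n_planes = 16,
                    n_cells = 20, seed = 42)
tis  <- generate_tissue(spec)
rec  <- quantify_stack(tis$stack)            # 3 projections -> 20 cells
res  <- apply_population_filter(rec, 2600 * 0.19, 2600 * 0.19)
res$log
#> # A tibble: 4 × 2
#>   stage          n_cells
#>   <chr>            <int>
#> 1 input               20
#> 2 outlier_filter      20
#> 3 edge_removal        20
#> 4 deduplication       20

dplyr::select(res$kept[1:5, ], cell_id, body_area_um2, n_primary,
              n_segments, CI, CEA_um2)
#> # A tibble: 5 × 6
#>   cell_id       body_area_um2 n_primary n_segments    CI CEA_um2
#>   <chr>                 <dbl>     <int>      <int> <dbl>   <dbl>
#> 1 sv0_cell_0001          28.5         5         19   3.8   1396.
#> 2 sv0_cell_0002          28.7         5         11   2.2    827.
#> 3 sv0_cell_0003          28.6         5         21   4.2   1386.
#> 4 sv0_cell_0004          28.5         5          9   1.8    701.
#> 5 sv1_cell_0001          24.6         4         12   3      461.
```

Each row is one cell: `body_area_um2` its soma area, `n_primary` the
processes leaving the soma, `n_segments` all process stretches between
nodes (soma root, branch point, tip), `CI` their ratio — cell 1 carries
on average 3.8 segments per primary process, cell 4 barely branches —
and `CEA_um2` the hull area over the process tips, the territory the
cell surveys. Against the generator's truth table (`tis$truth`) the
branch counts match exactly and the areas within a few percent.

Cluster a larger simulated survey and read off phenotype proportions:

```r
sim <- simulate_feature_table(2000, mix = c(0.70, 0.18, 0.11, 0.02),
                              seed = 1)
fit <- kmeans_ci_cea(sim, k = 4, seed = 0)
tidy(fit)
#> # A tibble: 4 × 5
#>   cluster    CI CEA_um2 frequency  size
#>     <int> <dbl>   <dbl>     <dbl> <int>
#> 1       1  3.01    380.     0.692  1385
#> 2       2  7.53    375.     0.172   343
#> 3       3  2.97   1499.     0.115   230
#> 4       4  7.46   1489.     0.021    42

cut <- compute_cutoffs(sim)
freq <- subpopulation_frequencies(assign_subpopulations(sim, cut))
round(unlist(freq[c("SP1", "SP2", "SP3", "SP4")]), 3)
#>   SP1   SP2   SP3   SP4
#> 0.687 0.175 0.116 0.022
```

The planted 70/18/11/2 % mixture is recovered both by k-means and by
the cutoff quadrants. And the sample-size calculator, on published-style
group summaries (cytoplasm area 74.4 vs 149.4 µm², σ = 42.2):

```r
required_sample_size(74.4, 149.4, 42.2)
#> [1] 7
```

— seven animals per group to resolve a two-fold cytoplasm change by a
conventional two-sample test at α = 0.05 and power 0.90.

A thin command-line front end over the same functions ships in
`inst/cli/micromorph` (subcommands `simulate`, `project`, `quantify`,
`filter`, `cluster`, `subpop`, `stats`, `map`).

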