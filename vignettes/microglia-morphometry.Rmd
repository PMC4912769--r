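---
title: "Microglial morphometry and phenotypic clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microglial morphometry and phenotypic clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromorph)
```

## The measurement problem

Microglia are the resident macrophages of the central nervous system. In
the healthy brain most of them are *ramified*: a small soma bearing a
tortuous, branched arbor of thin processes that continuously samples the
surrounding neuropil. Under inflammatory challenge the arbor remodels, in
the extreme down to the *amoeboid* form — a large soma with at most a
couple of unbranched stubs. Because morphology tracks function, per-cell
morphometry over tens of thousands of cells is a practical readout of
microglial state, but it requires an automated chain from fluorescence
image stacks to per-cell numbers, and statistics that respect both the
animal level (a handful of mice) and the cell level (thousands of cells
per mouse).

`micromorph` implements that chain for GFP-type single-channel confocal
material: sub-volume maximum-intensity projection, soma and
process-network segmentation, per-cell criteria, population filtering,
quadrant/k-means phenotyping, group statistics, and a sample-size
calculator. A synthetic-tissue generator with exact per-cell ground truth
backs every stage, so the whole pipeline is testable without a
microscope.

## Per-cell criteria

For each cell the pipeline reports soma area and roundness, cytoplasm
area (soma plus the stroke area of the order-1 processes), mean
fluorescence over the whole cell (background-subtracted), ramification
counts by branch order, total ramification length, and two derived
indexes:

* **Complexity index (CI)** — the number of *segments* (stretches of
  process between two nodes: soma root, branch point, or tip) divided by
  the number of *primary* ramifications (those leaving the soma). CI is
  the mean branching complexity per primary process; an unbranched cell
  has CI = 1, and CI = 1 is the operational definition of the amoeboid
  phenotype (no branch nodes).
* **Covered environment area (CEA)** — the planar territory spanned by
  the process extremities, in µm². The defining phrase "polygon over
  the process extremities" fixes no vertex order; the convex hull is the
  unique order-free reading, and it is also monotone under adding
  extremities, so that is what `covered_environment_area()` computes.

Roundness is `4πA/P²`, 1 for a disc. Because the soma mask is a pixel
set, both `A` and `P` are measured on its ordered boundary chain after a
3-point circular moving average — the smoothing removes the staircase
excess that makes raw chain lengths overestimate curved boundaries,
while barely rounding true corners. On digitised discs this scores
≥ 0.97, on squares
about π/4, and on a 1:4 rectangle about 0.50 — so the 0.7 population
cutoff separates compact somata from elongated debris the way the
analytic values suggest. The normalisation constant is a declared
convention, not something the measurement itself pins down.

## Imaging geometry

The acquisition model is a spinning-disc confocal stack: fields of
920 × 920 px at 0.19 µm/px, 16 focal planes 2 µm apart (30 µm of
tissue), tiled into mosaics of up to 10 × 10 fields (≈ 3 mm² per
region). Each stack is split into three contiguous axial blocks of as
equal size as possible — earlier blocks larger, so 16 planes split
6/5/5 — and each block is reduced by maximum-intensity projection.
Sharing a boundary plane between blocks was rejected: a cell imaged in
the shared plane would be guaranteed to appear in two projections,
which would make the downstream duplicate-elimination semantics murky.
Analysis is strictly 2D; the z-step is metadata only.

## Segmentation

Somata are found by thresholding a lightly smoothed projection,
morphologically opening the foreground with a 2 µm radius (which erases
the thin process meshwork), and labelling what survives. Each blob is
then refined to its half-maximum contour, which recovers the soma
boundary irrespective of how generous the global threshold was.

The global threshold itself deserves a note. Otsu's method — the
default reach in this setting — assumes a meaningfully bimodal
histogram. On a mosaic where cells cover one or two percent of the
pixels the between-class variance is maximised *inside* the background
distribution, and under realistic noise that mislabels most of the image
as foreground. The default is therefore a background-referenced rule:
the median and MAD of the (smoothed, subsampled) image estimate the
background level and noise, and the cut is placed
`median + max(6·MAD, 0.25·(p99.9 − median))` — a noise-safe margin above
background, but at least a quarter of the way towards the bright-signal
reference so the blur skirt of thin strokes stays out. Otsu (computed on
log-intensities) remains available via
`segmentation_params(global_threshold_method = "otsu")`.

Processes are segmented by carving a 0.6 µm guard band around each
detected soma out of the foreground (so each primary process becomes its
own skeleton stem), thinning the remainder to a one-pixel skeleton, and
converting that to a geometric graph. Thinning uses the Guo–Hall
two-subiteration scheme; the more common Zhang–Suen scheme deletes
two-pixel-wide diagonal strips outright, which in practice erased whole
diagonal stubs and stems. Graph cleanup — merging junction clusters
closer than 1.2 µm along the skeleton, pruning spurs shorter than
0.9 µm that hang off a junction, removing sub-2 µm self-loops at
junctions, and dissolving the degree-2 nodes those moves leave behind —
iterates to a fixpoint, because each move can expose work for the
others. Isolated short edges are kept whatever their length: they are
real stubby processes (the amoeboid phenotype), not artefacts.

Each connected skeleton component is rooted at the soma whose contour it
approaches within the attribution gap (1 µm, over and above the guard
band); components reachable from no soma are reported *unattributed*,
and a component touching two somata is split along the skeleton by
shortest path. Branch orders then follow the topology: soma-incident
segments are order 1, the order increments at each junction, and orders
≥ 3 are folded into the tertiary count (only three orders are reported).
A root-to-first-junction stretch counts as one segment — the only
convention under which an unbranched cell has CI exactly 1.

## Population filtering

Three rules clean the feature table before statistics: somata outside
10–500 µm² or with roundness below 0.7 are rejected as tissue-noise
artefacts (boundary values are kept — the rules are strict
inequalities); cells whose extremity hull or soma touches the mosaic
border band (default width 0: touching suffices) are removed as
potentially truncated; and duplicate detections of one cell on two
*adjacent* axial sub-volumes — centroids within 5 µm, about one soma
radius — are merged, keeping the larger soma (ties go to the lower
sub-volume, deterministically). Centroid proximity rather than mask
overlap is a declared, configurable choice; nothing in the duplication
mechanism requires more.

## Phenotypic clustering

Clustering operates on (CI, CEA) only, after a correlation screen
(Pearson, Spearman, two-feature PCA) confirms the two indexes are not
collinear — they measure complexity and territory, which are logically
independent, and a warning is raised if |r| > 0.7. Amoeboid cells are
excluded by default and treated as their own phenotype;
`include_amoeboid = TRUE` restores them for sensitivity analysis.

k-means (k = 4, Lloyd) runs on z-scored features — CEA is two to three
orders of magnitude larger than CI and would otherwise own the squared
distance — with k-means++ seeding and `n_init = 10` restarts, keeping
the lowest within-cluster sum of squares; clusters are renumbered by
descending frequency. In parallel, quadrant *sub-populations* SP1–SP4
are defined by control-group mean cutoffs: SP1 low CEA/low CI, SP2 low
CEA/high CI, SP3 high CEA/low CI, SP4 high CEA/high CI, with "high"
meaning strictly above the cutoff (boundary cells are low). Cutoffs are
cell-pooled means over the non-amoeboid control cells, not per-animal
means of means, because the clustering itself is cell-level. On cleanly
separated mixtures the two views agree on ≥ 90 % of cells.

## Statistics

Animal-level comparisons use a Shapiro–Wilk gate (α = 0.05 per group):
both groups normal → two-sided Student's t (pooled variance), otherwise
a two-sided Mann–Whitney test, exact for group sizes up to 12 without
ties. Inter-region variability uses Kruskal–Wallis; sub-population
distributions use a χ² test on the 2 × m count table; correlations are
Spearman. No multiple-testing correction is applied, matching the
conventional analysis the package mirrors.

The sample-size calculator answers "how many animals per group would a
conventional two-sample comparison need": with common standard deviation
σ, two-sided α and power 1 − β,

n = ceiling( 2 (z₁₋α/₂ + z₁₋β)² σ² / (m̄_A − m̄_B)² ).

At the defaults (α = 0.05, power 0.90) the multiplier is ≈ 10.507, and
the ceiling — not rounding — is what makes the calculator reproduce the
published per-criterion designs exactly. The normal-approximation
multiplier is a deliberate choice over an iterated noncentral-t solver;
it is the form that the published table entries are consistent with.

## The synthetic-tissue generator

Every stage is validated against `generate_cell()` /
`generate_tissue()` / `generate_cohort()`, which grow cells with known
truth and render them into image stacks:

* **Archetypes.** Five parameter bundles: four ramified forms spanning
  low/high CI (branching probabilities ≈ 0.70/0.45/0.25 vs
  0.85/0.75/0.50 per order) × low/high CEA (order-1 segment length
  7.5 vs 11 µm, decaying 0.8× per order), plus an amoeboid form (larger
  soma, two unbranched ≈ 6 µm stubs, CI = 1 by construction). The
  quantitative values are the generator's own calibration; they are
  chosen so CI sits in the 4–8 range and CEA in the 400–1200 µm² range
  and so the published regional orderings (cerebellar microglia lower in
  CI and CEA than cortical ones; cortex densest and least amoeboid) are
  preserved by the region presets. Segment lengths are floored at
  3.5 µm: at 0.19 µm/px, shorter segments are not resolvable against the
  stroke width, and the floor keeps the ground truth attainable by *any*
  correct segmentation rather than encoding our own.
* **Geometry.** Processes are smoothed random-walk polylines with
  bounded turning; each primary arbor is confined to its own angular
  sector so arbors never self-cross; sibling branches diverge by
  0.62–0.82 rad. A clearance check regrows the rare tree whose
  non-adjacent branches come closer than one stroke width, whose arbor
  re-enters a 2.3 µm band around the soma (which would read as a phantom
  primary downstream), or which leaves the 34 µm extent cap; growth
  near the cap truncates segments and stops branching when no
  detectable child would fit.
* **Tissue.** Cells are placed by rejection sampling with a 70 µm
  minimum centroid spacing (twice the extent cap, so arbors of
  neighbours never overlap and the truth stays unambiguous), assigned to
  one of the three axial sub-volumes, rendered into every plane of that
  sub-volume, and covered with per-plane additive Gaussian noise over a
  constant background.
* **Cohorts.** Treated animals have soma radius scaled by √f and stroke
  width by f (default f = 2), so body and cytoplasm areas both scale by
  exactly f — a two-fold cytoplasm enlargement with untouched branching
  topology. Each animal also carries a lognormal size effect
  (σ = 0.15 on the log scale) so animal-level summaries have biological
  and not merely sampling variance. `detail = "counts"` samples only the
  branching process (no geometry; CEA is `NA`), fast enough for
  thousands of replicate cohorts; `detail = "tree"` adds polylines and
  endpoints; `"raster"` renders patches. The three levels share the
  branching and length distributions but are separate random streams,
  and the spatial extent cap applies only when geometry is grown.

What the generator does **not** emulate: optical point-spread blur along
z, photobleaching, uneven illumination, overlapping arbors of
neighbouring cells ("dense network" tissue), and touching somata.
Passing the recovery tests therefore demonstrates the correctness of the
measurement chain on resolvable material, not that segmentation of
heavily entangled real tissue is solved — on real mosaics the edge and
duplicate filters, the unattributed-process channel, and parameter
tuning (`smoothing_sigma_um` up under noise) carry that weight.

## Numerical and design choices worth knowing

* Thinning is Guo–Hall; dead-end walks during graph tracing close at
  synthetic endpoint nodes (never discarding pixels), and short strokes
  that thin to closed rings are traced as self-loop segments rather than
  lost.
* Binary morphology runs on an exact Euclidean distance transform;
  Gaussian smoothing is a separable convolution; thresholds are
  estimated on a ≤ 10⁶-pixel subsample of the smoothed image.
* Problem sizes in the shipped validation: branch-count recovery is
  scored on 200 cells across ten 2600² px noise-free mosaics (exact
  recovery of all four counts for ≥ 99 % required, currently 100 %) and
  100 cells at signal-to-noise 5 (primaries within ±1 for ≥ 95 %);
  clustering recovery on 2000-cell mixtures; the two-group test's level
  on 2000 null cohorts of 7 + 6 animals and its power on 200 cohorts
  with the two-fold cytoplasm effect. These sizes are the package's
  validation design and are reproduced by `scripts/acceptance.R`.
* Degenerate inputs: blank projections return empty detections (not
  errors); cells whose processes are all pruned are classified amoeboid
  with CI = 1; constant clustering features, empty control sets, equal
  means in the sample-size formula, and sub-3-animal groups all raise
  descriptive errors before any computation.

## Known limitations

2D only (a cell's axial structure is collapsed by the projection);
no watershed splitting of touching somata; centroid-based (not
mask-overlap) duplicate matching; k fixed at 4 in the published design
(configurable, but no model-selection machinery); no multiple-testing
correction by design. The synthetic generator's realism limits are
listed above and bound what the green test suite can claim about real
tissue.
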