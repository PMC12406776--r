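# astroseg

Quantifying astrocyte morphology and mitochondrial distribution from
two-channel fluorescence microscopy.

Astrocytes grow elaborate branched arbors whose finest, most distal
processes contact synapses, and their mitochondria fragment and
redistribute into those fine branches as the arbor matures.  Measuring
this — how many branches of each order a cell has, and how many
mitochondria of what size sit in each branch class — is tedious and
subjective by hand.  `astroseg` automates it for the common experimental
readout: a cell-fill channel (e.g. EGFP) and an organelle channel (e.g.
MitoDsRed) imaged in 2-D.

## What the package computes

**Detection.** Bright regions are candidate nodes of a *component tree*
(the nesting of connected upper-threshold components across intensity
levels).  Each candidate is scored with an order-statistics significance
score against its 2-px boundary ring,

```
z = (mean_in − mean_ring) / (σ · sqrt(1/n_in + 1/n_ring))
```

with σ a robust noise estimate from adjacent-pixel differences.  Along
every root-to-leaf chain of the tree the best-scoring candidate that
passes the significance, area and noise-cluster-existence gates is
selected.

**Linkage.** Intensity is rarely uniform inside a cell, so the initial
detection is fragmented.  Every fragment pair is connected by its
*brightest path* — the 8-connected pixel path maximising the minimum
intensity en route — and the fragment graph weighted by each path's mean
intensity is resolved with an optimal (maximum-weight) spanning tree.
Tree edges brighter than a threshold merge fragments into one cell mask.

**Branch hierarchy.** The mask is thinned to a medial-axis skeleton with
a per-pixel local width (2·EDT − 1), decomposed at branchpoints, and
every branch is classified into four types from width and topology:
soma + primary processes, secondary processes, fine processes, and the
terminal tips of processes.

**Organelles.** Mitochondria detected in the second channel are binned
into these branch types by pixel plurality over the geodesic territory
map of the arbor.  Counts and mean sizes are reported for secondary,
fine and terminal branches; soma/primary mitochondria are excluded from
measurement (they form an unresolvable network there) and only counted.

**Organization metrics.** Nearest-neighbor distances and mean distance
to the k = 9 nearest neighbors for soma point sets, cluster areas of a
blurred, thresholded projection (strictly above a 500-px floor), and the
two-sample Kolmogorov–Smirnov statistic.

**Synthetic benchmark.** A seeded generator draws branched arbors with
known branch types, widths and mitochondrial placements, renders them
as two 16-bit channels with optional noise, and emits full ground-truth
label rasters — so every stage of the pipeline is testable without
external data.

## Worked example

```r
library(astroseg)

sim <- simulate_astrocyte(seed = 42, noise_sd = 0)   # two-channel synthetic cell
res <- run_pipeline(sim$cell, sim$mito)
res$profiles
```

```
#> detect: sigma=0, 1 fragment(s)
#> linkage: 0 edge(s), 1 cell(s)
#> hierarchy cell 1: SOMA_PRIMARY=5 SECONDARY=8 FINE=20 TERMINAL=20
#> organelle cell 1: 22 mitochondria (0 excluded)
# A tibble: 4 × 6
  cell_id type         branch_count mito_count mito_mean_size_px mito_mean_size_um2
    <int> <fct>               <int>      <int>             <dbl>              <dbl>
1       1 SOMA_PRIMARY            5         NA              NA                 NA
2       1 SECONDARY               8          6              14                 14
3       1 FINE                   20         12               8                  8
4       1 TERMINAL               20          4               7.5                7.5
```

The profile is the package's central result: one row per branch type
with the branch count, the mitochondrial count and the mean
mitochondrial size (px and µm²).  `SOMA_PRIMARY` rows report branch
counts only — mitochondrial measurements there are excluded by design.
Here the generator placed 6/12/4 mitochondria on
secondary/fine/terminal branches and the pipeline recovered exactly
those counts.  `tidy()`, `glance()` and `autoplot()` methods are
provided for profiles, arbors and neighbor statistics, e.g.
`autoplot(res$arbors[[1]])` draws the branch-type territory map.

A command-line front end is installed with the package
(`system.file("cli", "astroseg", package = "astroseg")`) with
subcommands `run`, `simulate`, `neighbors` and `clusters` over TIFF and
CSV files.

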