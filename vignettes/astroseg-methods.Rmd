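---
title: "Methods: segmentation, branch hierarchy and mitochondrial binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, branch hierarchy and mitochondrial binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroseg)
```

`astroseg` turns a two-channel fluorescence image of a branched
astrocyte into a per-cell profile: branch counts by hierarchy type and
mitochondrial counts and sizes per type.  This vignette explains the
underlying models, the parameters that matter, the numerical choices,
and what the synthetic benchmark does and does not establish.

## Detection by order statistics on a component tree

The detector treats an image as a family of nested bright regions: for
every intensity level, the connected components of pixels at or above
that level.  This *component tree* (4-connected by default; images with
more than 256 distinct values are binned to 256 levels for tree
construction, while all statistics use raw values) supplies the
candidate regions.  Each candidate is scored against its local
surround: with `mean_in` the mean over the region, `mean_ring` the mean
over the boundary ring (pixels within `ring_width = 2` px outside the
region), and `sigma` the noise scale,

$$z = \frac{\text{mean}_{in} - \text{mean}_{ring}}
          {\sigma\sqrt{1/n_{in} + 1/n_{ring}}}.$$

`sigma` comes from `estimate_noise()`: the median absolute difference
of adjacent pixels scaled to a normal standard deviation, computed
separately for the horizontal and vertical directions with the smaller
estimate kept.  Differencing cancels smooth structure; taking the
directional minimum makes the estimate immune to a ramp along one axis.
It assumes bright objects cover a minority of pixels.

A candidate is selected when it is the best-scoring member of its
root-to-leaf chain and passes three gates:

* **Significance**: $z \ge \Phi^{-1}(1-\alpha)$ with $\alpha = 0.001$.
* **Contrast floor**: contrast at least `min_contrast = 2` sigma.
  Threshold components are, by construction, upper tails of the local
  intensity distribution, so even pure-noise candidates show a positive
  contrast of roughly 1.5–2 sigma (the truncated-normal mean bias);
  the floor removes that bias cheaply.
* **Noise-cluster existence**: the expected number of 4-connected
  clusters of the candidate's area at its defining level (the minimum
  intensity over the region) in a pure-noise image must not exceed
  $\alpha$.  We bound it by $n\,(\lambda p)^A/(1-\lambda p)$, where $p$
  is the upper-tail probability of the level relative to the image
  median, $A$ the area, $n$ the pixel count, and $\lambda \approx
  4.063$ the growth constant of 4-connected lattice animals.  This is
  the step that controls the selection bias of scanning every threshold
  component: a near-percolation component covering most of a noise
  image, and small upper-tail speckle clusters, are both rejected,
  while any region a noise field essentially cannot produce is
  certified.  The published selection-bias correction for
  order-statistics region scores addresses the same issue; we implement
  this simpler existence bound and keep the plain two-sample $z$ as the
  reported score.

Overlapping selections (necessarily nested) are resolved in favour of
the higher score, ties toward the larger region.  With `sigma = 0`
(synthetic, noiseless input) scores are infinite for any positive
contrast and objects with constant interior on constant background are
recovered pixel-exactly.

Degenerate inputs: a constant image yields one candidate with no
boundary ring, hence no detection; `score_region()` on a region
touching all borders errors with "no boundary context".

## Fragment linkage by brightest paths and a spanning tree

Intensity inside a cell is non-uniform, so detection yields fragments.
Every fragment pair is joined by its *brightest path*: the 8-connected
pixel path from one fragment to the other that maximises the minimum
intensity along it (a maximum-bottleneck path, endpoints included).
Among bottleneck-optimal routes we minimise total darkness — the sum of
(max intensity − pixel intensity) — which prefers bright and then short
routes, with remaining ties broken toward lower pixel index; the result
is deterministic.  The edge weight is the path's mean intensity.  The
search runs in C++ over a bounding-box envelope inflated by
`envelope = 50` px (set `Inf` to search the whole image).

The fragment graph is resolved with the maximum-weight spanning tree
(Kruskal, edges ordered by decreasing weight with lexicographic
tie-breaks) — equivalently the minimum spanning tree of the
brightness-inverted cost.  Maximising linkage brightness is the point:
fragments of one cell are connected through bright cytoplasm, not
through dim background.  Edges weaker than `min_link_weight` (default:
half the mean fragment intensity) are cut, and each remaining component
becomes one cell mask: fragment pixels plus the 1-px linking corridors.

## Skeleton, widths and the four branch types

The mask is thinned with Zhang–Suen thinning followed by a sequential
simple-point cleanup (parallel thinning leaves 2-px diagonal runs;
removing 8-simple border pixels whose neighbours stay connected thins
them to a true 1-px, topology-preserving line).  Local full width at a
skeleton pixel is `2·d − 1` px, with `d` the Euclidean
distance-transform value: the distance to the nearest background pixel
*centre* overshoots the mask boundary by half a pixel at each side.
Under this convention a 5-px bar measures 5 and a radius-10 disk about
19.

The skeleton is decomposed at branchpoints (degree ≥ 3; adjacent
junction pixels merge into one node).  Two artifact rules keep the
graph faithful: leaf spurs shorter than `prune_spurs = 3` px — raised
to the local junction width, since thinning a ribbon of width *w*
sheds spurs up to about *w* px — are pruned; and junction-to-junction
stubs shorter than 5 px of width comparable to the junction are
absorbed into the node (one true branchpoint split in two by thinning).
When an intensity image is supplied, leaf ends are also trimmed of
consecutive pixels below half-way between the mask and background
medians: under noise the detected mask sprouts short dim extensions
past the true process tip and the skeleton follows them.  All three
rules are no-ops on clean input.

Classification is a deterministic rule table:

1. the **soma** is the connected region of mask pixels whose
   distance-transform value is at least `theta_soma = 0.6` of the
   maximum, containing that maximum; its width is the mean skeleton
   width inside it;
2. branches incident to the soma (directly or through a junction node
   touching it) with mean width — measured outside the soma — at least
   `theta_primary = 0.35` of the soma width are **primary**; skeleton
   arcs running through the soma are first split at it, so two
   primaries joined across the soma count as two; wide segments
   connected onward through junctions extend the primary process
   without adding to its count;
3. the distal `L_tip = 5` px of every other leaf branch form a
   **terminal tip** segment;
4. remaining segments are **fine** when mean width is strictly below
   `theta_fine = 3` px, otherwise **secondary**.

The strict inequality in rule 4 makes an even-width ribbon classify by
its nominal calibre: a 4-px-wide process measures 3.0 under the width
convention and lands in `SECONDARY`, while a 2-px process measures 1.
Branch counting reports the soma plus the number of primary chains
(split primary segments connected through a non-soma junction count
once), and tip segments for `TERMINAL`.

Every mask pixel is then assigned to its geodesically nearest typed
segment (8-connected breadth-first propagation from skeleton seeds,
distance ties toward the lower segment id).  Junction-cluster pixels
seed with their widest incident segment — a branchpoint belongs to its
thickest process — and the soma region always seeds as soma.

## Mitochondrial binning

Mitochondria are detected with the same detector on the organelle
channel, with pixels outside the cell mask suppressed to the background
median (`min_area = 5`, `max_area = 2000` px: an organelle never spans
the arbor).  Detected regions are clipped to the mask and refined at
full width at half contrast: pixels below half-way between the region
and ring means are excluded, so noise pixels riding just above the
detection level do not inflate measured sizes.  Each mitochondrion
takes the branch type holding the plurality of its pixels in the
territory map, ties toward the finer type.  Soma/primary assignments
are flagged excluded and reported only as a count — mitochondria form a
dense network there that cannot be resolved into discrete organelles —
and the conservation identity (reported counts + excluded = detections)
holds for every image.

## Organization metrics

`nearest_neighbor_distances()` and `k_neighbor_mean_distances()` (k
defaults to 9) are centre-to-centre Euclidean statistics over a soma
point set; no edge correction is applied, so border points are treated
like interior ones.  `cluster_areas()` maximum-projects multi-page
input, blurs with an isotropic Gaussian (radius 1 px by default, 0
disables), binarises at a caller-supplied threshold (the reference
workflow thresholds interactively, so no automatic default is offered)
and reports 8-connected component areas strictly above `min_area = 500`
px.  `ks_statistic()` enumerates all ECDF step points and returns the
supremum absolute difference only; inferential p-values are out of
scope.

## The synthetic benchmark

`arbor_spec()` defaults define the study conditions used throughout the
tests: a 512×512 16-bit canvas, a soma of radius 9 px (18 px wide),
4–6 primary branches of width 8 px and length 45–65 px, each branching
into 2–3 secondary branches (width 4, length 28–40) which branch into
2–3 fine branches (width 2, length 16–26), with a bounded random bend
of up to 15° per 3-px step.  Branch growth is self-avoiding: a child
polyline grows step by step and stops before colliding with previously
accepted centre-lines (its own parent and the shared start
neighbourhood exempt); a boxed-in sibling set is redrawn, and if the
geometry remains infeasible the children are dropped (all, or all but
at least two, so junction topology stays truthful and a parent without
children is a genuine leaf).  This guarantees the rendered image has
exactly the branch topology recorded as ground truth.

Mitochondria (defaults: 6 secondary, 12 fine, 4 terminal per cell,
echoing the enrichment of small mitochondria in fine processes) are
placed as ellipses elongated along their host branch, minor axis capped
by the branch width, with junction-aware margins — 1.5 parent-widths
from the proximal branchpoint, 8 px (or the tip window) from the distal
end — so the intended type of every placement is unambiguous; ground
truth records the *rendered, mask-clipped* pixel count, which is what a
perfect detector would measure, and placements covering fewer than 5
in-mask pixels are rejected.  Rendering draws constant-intensity
ribbons (cell +180 over a 120-count background, mitochondria +200) and
adds seeded additive pseudo-normal noise, rounded and clipped to the
16-bit range.  The background offset is large enough that realistic
noise levels do not clip at zero, mimicking a camera pedestal.

Validation uses zero-noise rounds (pixel-exact recovery expected:
mask IoU ≥ 0.95, per-type branch counts within ±1, mitochondrial counts
exact) and a stress round at noise sd 36 — one fifth of the cell
intensity — on a 352×352 canvas, 20 seeds, where per-type mitochondrial
counts agree within 10% and mean sizes within 15% in aggregate.  The
noisy study uses the smaller canvas simply to keep many replicates
cheap; the arbor is unchanged and fits either canvas.

What the generator does **not** emulate: optics (no point-spread
function, so object edges are a single pixel sharp), multiplicative or
Poisson-dominated noise (a Poisson option would change the
noise-estimate assumptions), overlapping arbors of multiple cells,
intensity gradients within a cell, and 3-D structure.  Passing the
round-trip therefore shows the chain of algorithms is correct and
calibrated under its stated model, not that it matches any particular
microscope's error profile.

## Parameter summary

| parameter | default | unit | role |
|---|---|---|---|
| `alpha` | 0.001 | – | significance level; also the noise-cluster existence budget |
| `ring_width` | 2 | px | boundary ring for the score |
| `min_contrast` | 2 | sigma | truncation-bias floor |
| `cell_min_area` / `mito_min_area` | 50 / 5 | px | area gates |
| `cell_max_area` | ¼ of image | px | a single cell never fills the field |
| `mito_max_area` | 2000 | px | an organelle never spans the arbor |
| `envelope` | 50 | px | brightest-path search margin |
| `min_link_weight` | half mean fragment intensity | counts | linkage cut |
| `theta_soma` | 0.6 | of max EDT | soma region |
| `theta_primary` | 0.35 | of soma width | primary gate |
| `theta_fine` | 3 | px | fine/secondary split (strict `<`) |
| `L_tip` | 5 | px | terminal tip length |
| `prune_spurs` | 3 | px | spur floor (width-adaptive) |
| `pixel_size` | 1 | µm/px | µm² conversions |

All of these are `pipeline_config()` keys; unknown keys are rejected
and the configuration is echoed into the output directory for
provenance.

## Known limitations

* Detection assumes additive, roughly Gaussian noise and objects
  covering a minority of pixels; heavy clipping at zero biases the
  noise estimate downward.
* The existence certification is conservative near background levels
  (where the lattice-animal bound cannot certify anything), so
  extremely faint extended structure below ~2 sigma contrast is
  invisible by design.
* Overlapping arbors are not untangled; each connected mask is treated
  as one cell.
* Terminal tips are tip *segments* of leaf branches, not whole
  branches — fine and terminal structures are counted separately, which
  matches reporting branch numbers per type, but means a leaf shorter
  than `L_tip` is entirely terminal.
* Coordinates in all tables are 0-based with row 0 at the top, matching
  the image-file convention; linear indices inside R remain 1-based.
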