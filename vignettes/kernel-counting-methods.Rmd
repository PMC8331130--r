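---
title: "Counting and measuring touching kernels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and measuring touching kernels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelseg)
```

## The problem

High-throughput phenotyping of grain kernels (and colonies, spores, cells)
starts from a photograph of many small objects on a contrasting background.
Two things make this hard. First, the pixels of interest (POI) must be
separated from background, shadows and debris without asking the user to
hand-pick a color index. Second, objects that touch fuse into single
connected components and must be split — and the splits that go wrong must
be repairable. `kernelseg` addresses both with a two-level filtering stage
(PCA over color features, then one-dimensional K-Means) and a
divide-and-combine segmentation driven by user-set size thresholds.

## Level one: color indices and correlation PCA

Each pixel carries 15 features: the raw `R`, `G`, `B` intensities and
twelve derived color indices — four families instantiated on each channel
with the cyclic order R → G → B → R. For primary channel $X$ with cyclic
successor $Y$ and remaining channel $Z$:

| family | formula | character |
|---|---|---|
| `PAT` | $X/(X+Y)$ | proportion among two bands |
| `DIF` | $2X-Y-Z$ | excess-channel difference, sign-carrying |
| `ROO` | $X/Y$ | ratio over other |
| `GLD` | $(X-Y)/(X+Z)$ | asymmetric normalized contrast |

Every division is guarded: a zero denominator yields 0, so a pure-black
pixel has all twelve indices equal to 0 and every plane is finite. The
registry is an ordinary named list, so alternative definitions can be
swapped in with `register_index()` without touching anything downstream.

PCA runs separately on the RGB block and the index block. Because raw
channels live on 0–255 while index values range from negative to positive
on image-dependent scales, the decomposition uses the **correlation**
matrix — every column is standardized before eigen-decomposition — so no
column dominates through its units. Eigenvector signs are fixed (largest
loading positive), which makes scores bit-stable and removes the usual
eigen-solver sign ambiguity. Score fields are rescaled linearly to 0–255
gray (min → 0, max → 255, round half-up; a constant field maps to all-zero
with a warning). The user picks one index PC (PC1 by default, since it
carries the most variance) and may blend in RGB PC1 or PC2 with a weight on
a 0.02 grid. Blending operates on the displayed 0–255 gray images, not raw
scores: raw-score mixing would let whichever block has larger score
variance dominate regardless of the weight.

## Level two: exact one-dimensional K-Means

The selected gray image is classified pixel-wise into $k \in 1..10$
clusters. Since the feature is a single 8-bit value, clustering is done on
the at most 256 distinct gray levels weighted by their pixel counts, and
the optimal 1-D clusters are contiguous in sorted order. `kernelseg`
therefore computes the *global* within-cluster-sum-of-squares optimum by
dynamic programming, $O(k\,m^2)$ for $m \le 256$ levels. This removes the
usual initialization/restart machinery entirely: there is no seed
sensitivity to document because there is no randomness — identical inputs
give identical labels, and equal-cost partitions resolve to the earliest
break points. Labels are renumbered by ascending cluster mean, so cluster
0 is always the darkest. The POI mask is the union of user-selected
clusters, optionally restricted to an elliptical region of interest
(pixel-center test, 0-based coordinates).

## The divide-and-combine segmentation

All connectivity is 8-connectivity throughout: two pixels touching only
diagonally belong together, matching the eight-neighbor boundary rule used
in shrinkage.

1. **Components.** Breadth-first-search flood fill labels every POI pixel;
   ids are dense in raster order of first discovery.
2. **Lower-bound pruning.** Segments with area below `area_min` or
   bounding-box diagonal below `diag_min` are removed permanently — these
   are specks and debris.
3. **Mean object area** is taken from the segments currently inside all
   four bounds ("correctly segmented objects"). If none qualify the mean of
   all segments is used, with a warning.
4. **Splitting.** Every segment above `area_max` or `diag_max` is a fusion
   suspect. The expected child count is `round(area / mean_area)` (half-up,
   floored at 2 — a region is only split when suspected multiple). The
   watershed path is tried first, boundary shrinkage as fallback; a segment
   neither can split is retained with the note `"unsplittable"` rather than
   silently kept or dropped.
5. **Merging.** Fragments below a lower bound that were produced by
   splitting are merged into the sibling sharing the longest 8-adjacency
   border, repeatedly, until the union satisfies the bounds; a fragment
   with no sibling neighbor is deleted.
6. Ids are renumbered densely; re-running the pipeline on an easy scene
   (nothing above the upper bounds) reduces exactly to prune+label.

### Watershed with a shrinking marker search region

The Euclidean distance transform (EDT) of a fused segment peaks near each
object's center. Markers are local maxima of the EDT over a square window
whose area is the current *search region*. The region starts at the mean
object area and **halves** each iteration while fewer markers than the
target are found, stopping when the region reaches one pixel; halving (as
opposed to a fixed subtractive step) is what lets the region actually
"reduce to one". Marker-controlled watershed then floods the negated EDT
from the final markers by priority flood, deepest pixels first, with FIFO
tie-breaking for exact determinism; basins become children and partition
the parent's pixels exactly.

Digitized EDTs need two safeguards, both of which matter in practice:

- **Plateaus and regional maxima.** A plateau of equal maxima contributes
  one marker at its centroid. A candidate plateau is extended through all
  equal-valued neighbors; if the extended plateau borders a strictly
  greater pixel it lies on the flank of a ridge — a digitization artifact,
  not a peak — and is discarded.
- **Prominence (dynamics).** Surviving candidates are flooded into basins,
  and a basin whose peak rises less than $h = 0.4$ EDT units above the
  saddle shared with a deeper basin is merged into it. The two populations
  this separates are well apart: quantization twins on a ridge differ by a
  couple of $\sqrt{n+1}-\sqrt{n}$ steps ($\le\!\approx\!0.25$ at typical
  depths), while genuine object lobes rise at least $\approx 0.5$ above
  the contact-neck saddle even for objects touching flank-to-flank. The
  value 0.4 was calibrated once on synthetic tangent-pair scenes and sits
  centered in that gap. The same machinery caps the basin count at the
  target (weakest prominence merged first), since the marker count decides
  the number of objects.

Without these safeguards the engine both over-splits (a pair of
above-average seeds gets target 3 and a manufactured third marker) and
under-splits (a true weak lobe suppressed); with them, the only fusions
left behind are pairs whose joint distance ridge is genuinely continuous —
two equal objects overlapping along their long flanks — which no
distance-based watershed can separate. Those are exactly the cases the
pipeline hands to boundary shrinkage, and when that also fails they are
retained with the `"unsplittable"` note.

### Boundary shrinkage and re-expansion

For fused objects whose rims have dents, the boundary — every pixel with at
least one background 8-neighbor — is peeled iteratively. Peeling stops when
the remnant divides into two or more components, fits the upper bounds, or
vanishes (the last two mean the segment is unsplittable this way). After a
split, all peeled pixels are re-enabled by assigning each to the
geodesically nearest remnant component via multi-source BFS, so children
partition the parent exactly. The classic fixture: two 5×5 squares joined
by a 1-pixel bridge lose the bridge in the first peel and re-expand into
two children split at the bridge midline; a solid 3×3 square peels to its
center pixel in one iteration.

## Morphometry and reference scaling

Length is the largest Euclidean distance between two boundary-pixel
centers (computed on the convex hull, which carries all extremes; ties go
to the first raster pair); width is the extent of boundary projections onto
the perpendicular axis. Distances are between pixel centers, so a 1×5 run
of pixels has length 4.0 and width 0.0 — the convention to keep in mind
when comparing against calipers. Projection-extent width equals the longest
perpendicular chord for convex shapes and is deterministic for concave
ones.

Any retained segment of known physical area can serve as the scale
reference — only its total area matters, not its shape. The area ratio is
$\mathrm{mm^2/px} = A_{ref,mm^2}/A_{ref,px}$; linear measurements use its
square root, the unique dimensionally consistent extension. Reference
scaling is deliberately unavailable in batch mode, where no per-image
selection step exists; batch outputs stay in pixels.

## The synthetic scene generator

`generate_scene()` renders rotated ellipses with flat fill color plus
per-pixel Gaussian noise on a light (235) or dark (20) background,
optionally with tangent pairs, circular specks (capped below 20% of the
smallest object), a known-area reference disk, and a "wrinkled" boundary
mode (sinusoidal perturbation) that exercises the shrinkage path. Tangent
pairs are placed by walking the partner inward along the line of centers
from the analytic tangency distance until the rendered pixel sets become
8-adjacent; every pixel keeps exactly one true owner, so truth areas equal
rendered pixel counts identically. Defaults model a single-variety seed
lot: mean semi-axes 9 × 5 px with sd 0.5 × 0.35, i.e. ~8% area CV — tight
enough that the singleton and pair area distributions separate, which is
the premise behind setting `area_max` between the largest singleton and
the smallest pair (≈1.5× the median singleton area).

What the generator does *not* emulate: specular highlights, soft shadows,
perspective and lens distortion, anti-aliased edges, within-object color
texture, and overlapping (not merely touching) kernels. Passing tests
therefore demonstrate the engine's algorithmic correctness and its
behavior under controlled adjacency and noise — not robustness to every
photographic artifact of real seed images.

## Numerical choices and degenerate inputs

- Zero-denominator color indices → 0; constant gray fields → all-zero
  image with a warning; constant feature columns are dropped from PCA with
  a warning, and an all-constant block is an error.
- Eigenvalues below 1e-10 are treated as zero; `round_half_up` is used
  wherever a rounding convention matters (gray rescale, child-count
  estimate).
- `k` larger than the number of distinct gray values is reduced with a
  warning; equidistant K-Means boundary values join the lower-mean cluster.
- Segments touching the canvas edge are padded with one background pixel
  before the EDT so edges behave like interiors.
- All tie-breaks (BFS discovery order, flood insertion order, marker
  centroid selection, merge-partner choice) are fixed in raster order, so
  every stage is deterministic and byte-reproducible from the emitted
  parameter file.

## Problem sizes used by the test suite

The suite validates counting on scenes of 100–1,000 objects (canvas sizes
550–1600 px, five seeds per size), tangent-pair recovery on ten 200-object
scenes with 20% of objects in pairs, oracle equivalences on 200 random
64×64 masks (union-find), 10,000-pixel PCA fixtures, and 50 K-Means trials
against exhaustive search. These sizes keep a full run to a few minutes
while covering every splitting path; the engine itself has no intrinsic
size limit beyond memory.

## Known limitations

- Pairs of similar-size objects fused along their long flanks can present
  a continuous distance ridge and no rim dent; neither watershed nor
  shrinkage separates them (about 1 scene in 25 loses a single count to
  this in the tangent-pair tests). They are retained with the
  `"unsplittable"` note for the user to resolve by deletion or threshold
  adjustment.
- Width is measured on the visible silhouette; kernels resting at an angle
  show a narrower silhouette than their true maximum width, and no pose
  correction is attempted.
- Only 3-channel RGB input is supported; multispectral images are out of
  scope.
- No skew or perspective flattening is performed: flattening changes
  length/width ratios and requires in-image boundaries.
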