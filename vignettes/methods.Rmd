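---
title: "Methods: from registered tissue blocks to anatomical-structure cell-type populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from registered tissue blocks to anatomical-structure cell-type populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpop)
```

## The problem

Single-cell datasets are routinely annotated with cell types, but rarely with
a precise 3D location. When a tissue block *is* spatially registered — as a
cuboid extraction site placed inside a reference organ — the cell-type
composition of the dataset can be projected onto the anatomical structures
(ASs) the block overlaps. Aggregating many such datasets yields, for every
anatomical structure, a cell-type population: how many cells of each ontology
term one expects to find there, split by donor sex and annotation tool.

`ctpop` implements that construction end to end: mesh geometry and collision
detection, a quality gate for datasets, population algebra with ontology
crosswalking, corridors of plausible tissue origin, and a synthetic-data
generator that makes the whole pipeline testable offline with exact ground
truth.

## Geometry

All geometry lives in a right-handed millimeter frame, the frame of the
reference organ's meshes. An extraction site is a cuboid with edge lengths
$(d_x, d_y, d_z)$, a rotation, and a translation. The rotation convention —
intrinsic X-then-Y-then-Z Euler angles in degrees, applied about the cuboid
*center*, followed by a translation of that center — is a package convention:
registration formats in the wild do not state one unambiguously, so we fix it
once and use it consistently in readers, writers and fixtures. Every
consumer of site JSON written by this package sees the same convention, and
the tests exercise it directly (a 90° yaw swaps the x and y extents; volume
is rotation-invariant to 1e-9 relative).

Enclosed volume uses the divergence theorem over the triangle surface,
$V = \tfrac{1}{6}\sum_T \det(v_1, v_2, v_3)$, and requires a closed mesh.
Closedness and edge-manifoldness are checked by counting directed edges:
closed means every undirected edge is used exactly twice, manifold means
never more than twice, consistent orientation means the two uses oppose.
Hole filling is deliberately conservative: only boundaries that decompose
into simple loops (each boundary vertex on exactly two boundary edges) are
capped, by fanning triangles around the loop centroid; anything else raises
an error rather than guessing a repair.

### Intersection volumes: exact path and brute-force oracle

The quantity everything downstream depends on is the intersection volume
between a placed cuboid and a structure mesh, reported as an absolute volume
in mm³ and as a percentage of the *site* volume (0–100).

Two independent routes compute it:

* **Exact (primary):** half-space clipping. The cuboid's triangle surface is
  clipped successively by each face plane of the structure
  (Sutherland–Hodgman polyhedron clipping); after each plane the planar
  cross-section of a convex solid is a convex polygon, so the cut is capped
  by ordering the intersection points angularly about the section centroid.
  The clipped, capped surface is closed, and its divergence-theorem volume is
  the intersection volume — exact up to floating point whenever both
  operands are convex. Convexity is verified (every vertex on or behind
  every face plane, at 1e-7 relative tolerance); non-convex structures fall
  back to the voxel route and are flagged in the output's `method` column.
* **Voxel brute force (oracle):** parity rasterization. Both meshes are
  voxelized on a shared grid spanning their bounding-box overlap: for each
  voxel-center column along z, ray–triangle crossings are accumulated and
  centers between successive crossing pairs are interior. The conjunction of
  the two occupancies, times pitch³, estimates the intersection volume. The
  default pitch is 1/40 of the smallest bounding-box edge of the smaller
  operand, which lands the estimate within about 2% on convex bodies.
  Sample columns carry a fixed sub-permille jitter so axis-aligned geometry
  never sits exactly on a face or edge; the jitter is deterministic, so the
  oracle is reproducible.

The two routes share no code beyond the mesh container, which is what makes
the oracle a meaningful cross-check: the acceptance suite compares them on
100 random cuboid-versus-convex-structure fixtures and requires agreement
within 2% relative.

## Collision detection

Detection is two-phase, as in any collision pipeline: a cheap axis-aligned
bounding-box broad phase (`bbox_collisions`), whose hits are by construction
a superset of the true ones, then the exact narrow phase (`mesh_collisions`)
on the survivors. Zero-volume contact — a site touching a structure's face —
is not a collision. Records are sorted by descending volume with
lexicographic ties on the structure id, so output order is deterministic.
Reference organs are audited separately for mutually intersecting structures
(`detect_reference_overlaps`); when structures overlap, a site in the shared
region simply receives full records for both, and the overlap is reported on
its own.

## Corridors

A corridor is the 3D region of all placements of an extraction site that
preserve its observed intersection volumes with the structures it collided
with, within a relative tolerance. The construction follows a three-case
rule on the number of collided structures:

1. **One structure:** the whole structure mesh is the corridor — the block
   could have come from anywhere inside it.
2. **Two structures:** a filter–search over translations. The *filter*
   stage approximates each target by its minimum bounding box and computes
   the admissible region $\Omega$ of center translations as the intersection
   of the Minkowski-expanded target boxes (each box grown by the site's half
   extents). The *search* stage slides the fixed-size, axis-aligned site
   over a grid of spacing `step` inside $\Omega$; a candidate is feasible
   when every re-measured target volume is within `tolerance` (default 0.1,
   i.e. 10% of the true intersection volume) of the observed one. The union
   of all feasible cuboids is then wrapped into a single closed surface.
3. **Three or more structures:** the site is considered pinned; the corridor
   is exactly the site cuboid.

Several choices here were genuinely open and are fixed as package defaults:

* **Step size.** The step trades corridor precision against search cost: too
  coarse skips feasible pockets, too fine explodes the candidate count, and
  since volumes are floats an exact-match criterion would accept almost
  nothing — hence the relative tolerance. The default step is 10% of the
  smallest site dimension; both step and tolerance are arguments (and CLI
  flags).
* **Grid anchoring.** The candidate grid is anchored at the original
  translation, so halving the step strictly refines the grid: every coarse
  feasible point survives refinement (tested).
* **Search space.** Only translations are searched; rotation and size stay
  fixed. Only the originally collided structures constrain feasibility;
  intersections newly acquired with other structures are not constrained.
* **Wrapping.** The union of feasible cuboids is voxelized at pitch
  `step/2`, dilated outward by `wrap_offset` (default `step/2`, a Chebyshev
  dilation), and surfaced by boundary-face extraction. This is an offset
  wrap in the same spirit as alpha wrapping: any backend meeting the
  containment-plus-closedness contract would do, and the tests check exactly
  that contract — the output is closed, and every feasible cuboid lies
  inside it (verified by an independent ray-parity point-in-mesh check).
* **Case 2 applies at exactly two structures, case 3 at three or more**, and
  case 1 returns the whole structure regardless of the observed partial
  intersection percentage — the enumeration is reproduced literally.

## Cell-type populations

A population is a list of (ontology id, label, count, percentage) entries
owned by a dataset, an extraction site, or an anatomical structure, and
produced by exactly one annotation tool — tools are never mixed inside one
population, only preferred between (Azimuth over CellTypist over popV when a
single population per dataset is wanted).

The algebra is small and closed under two invariants that every transform
must preserve: percentages sum to 100 (±1e-6) and crosswalking/rollup
conserve total cell counts (±1e-9).

* **Crosswalk.** Tool labels map to Cell Ontology (CL/PCL) terms with
  `exact` or `narrow` match semantics, stored verbatim; no ontology
  reasoning is attempted. Two source labels mapping to one target merge
  with counts summed. Labels with no mapping are retained, flagged
  `not_crosswalked`, and listed in an unmapped report — unmapped is data,
  not an error.
* **Rollup.** Counts pool under high-level parent terms; crosswalked types
  with no parent go to a `no_mapped_parent` bucket, never-crosswalked
  labels to `not_crosswalked`.
* **Similarity.** Populations are compared by weighted cosine similarity
  over percentage vectors on the union of their cell-type ids,
  $\sum w_i u_i v_i / (\sqrt{\sum w_i u_i^2}\sqrt{\sum w_i v_i^2})$, zero
  when either norm vanishes. Weights default to 1 — no weighting scheme is
  canonical, so uniform is the neutral default and weights are accepted as
  input. `predict_origin` ranks candidate origins by this similarity with
  lexicographic tie-breaks.
* **Z-scores.** For heatmap-style comparisons, each cell-type row of a mean
  percentage matrix standardizes as $Z = (x - \mu)/\sigma$ with population
  (divide-by-n) standard deviation; constant rows map to 0.

### Marker genes

Per cell type, genes are ranked by differential expression against the rest
of the dataset. The pipeline mirrors standard single-cell practice: per-cell
normalization to 10,000 total counts, log1p, then a standardized mean
difference (difference of group means over the pooled standard deviation,
with a 1e-9 floor against zero variance). No single test statistic is
canonical for this step across tools; the standardized mean difference was
chosen because it is symmetric, scale-free, and deterministic, and ties
break lexicographically by gene symbol so rankings are reproducible. The
top-n genes (default 10) are recorded with their mean in-group and mean
rest expression on the normalized log scale. Gene identifiers are
harmonized beforehand by a stable-id-to-approved-symbol lookup
(`normalize_gene_ids`), with unmatched identifiers passed through and
reported. QC summaries (`qc_gene_percentages`) follow the usual prefix
conventions — RPS/RPL for ribosomal, MT- for mitochondrial — as per-cell
percentages of total counts, summarized as mean/median/SD per dataset, with
all-zero cells excluded and counted.

## The atlas pipeline

`build_atlas` runs the whole construction deterministically from a
configuration (in-memory objects or file paths; YAML/JSON accepted):

1. **Collide** every referenced extraction site against its target organ.
2. **Gate** datasets: C1 registered site with structure tags; C2 a cell-type
   population exists; C3 the source is a QA/QC portal or a peer-reviewed
   publication; C4 healthy adult donor — disease status healthy, sex
   recorded, age recorded and strictly greater than 18. A per-source
   exemption (`adult_only_sources`) lets a source that attests adult-only
   donors pass C4 with an age range instead of a value. Separately,
   datasets under 100 cells are dropped (`MIN_CELLS`). Failures are data
   (a report), never errors.
3. **Build and crosswalk** dataset populations per (dataset, tool).
4. **Aggregate** to extraction sites (counts summed over co-registered
   datasets) and then to anatomical structures: each site's counts scale by
   its intersection percentage over 100 before summing, and weighted counts
   stay fractional — rounding is presentation-layer only. Aggregation is
   grouped strictly by (organ sex, tool). Aggregation is over raw weighted
   counts, not per-dataset percentages, so larger datasets contribute
   proportionally more cells.
5. **Report** gate outcomes, collision records, unmapped labels, and count
   tables (datasets / sites / structures / organs, split by sex and
   modality), and serialize populations as JSON and flat CSV.

All outputs are written with fixed formatting; two runs from the same
configuration and seed are byte-identical, CSVs and OFF meshes alike.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated; it is first-class, tested code:

* **Organs** are 1–n convex structures (boxes, icospheres at two
  subdivisions, triangular prisms) on a gapped line, pairwise disjoint
  unless an overlapping pair is explicitly requested. Convexity is a
  deliberate restriction: it keeps the interval-arithmetic and voxel
  oracles exact or tightly bounded, so fixture ground truth is analytic.
* **Sites** are placed fully inside one structure, straddling two or three
  neighboring boxes (with analytic interval-arithmetic intersection
  percentages recorded as ground truth), or disjoint from everything.
* **Cell datasets** draw labels from per-structure mixtures (400–1,000
  cells in the presets — enough for stable fractions, small enough for
  fast tests), and counts from a negative-binomial model (dispersion 0.3)
  with 3 exclusive high-expression marker genes per cell type (mean 25 in
  type, 0.05 outside, background 1) plus a few MT-/RPS/RPL genes for QC.
  The *realized* counts, not the expected mixture, are stored as ground
  truth, so end-to-end recovery can be asserted exactly.
* **Crosswalks** map tool-specific labels 1:1 to CL-style ids, with a
  controllable unmapped fraction and optional narrow merges; a parent map
  and a gene-id lookup complete the input set.

Two presets bundle these: `small` (3 box structures, 6 healthy-adult
datasets, fully contained sites — recovery is exact by construction) and
`kidney-like` (5 mixed-shape structures, straddling sites, and planted gate
failures: a minor donor, a missing sex, a non-QC source, an unregistered
dataset, a 50-cell dataset). Every generator is a pure function of its
arguments and seed.

What passing on these fixtures does *not* show: real organ meshes are
non-convex, often imperfectly closed, and far larger; real annotations
disagree between tools; real crosswalks are many-to-many curated tables.
The geometry falls back to the voxel route for non-convex structures (at
~2% volume accuracy rather than exact), repair handles only simple holes,
and the marker statistic is one reasonable choice among several — these are
the package's known limitations, and the fixtures are designed to validate
the computational contracts, not organ-scale realism.

## Numerical choices

* Volumes in mm³; percentages on the 0–100 scale with the extraction-site
  volume as denominator.
* Clipping tolerance 1e-12 of the coordinate scale; cap-point deduplication
  at 1e-9 of scale; zero-volume contact threshold 1e-12 of the site volume.
* Duplicate cell ids in one annotation table are an error, not a dedupe —
  they indicate an upstream splitting bug that silent deduplication would
  hide.
* Sorting everywhere is deterministic (volume-descending with lexicographic
  ties; grid anchored at the original site translation).
* Problem sizes in the test and acceptance runs — 100 random geometry
  fixtures, 50 in the acceptance script, 300–500 property cases per
  algebra invariant, presets with 6–10 datasets of 400 cells — were chosen
  so the full suite exercises every contract at desk scale in well under
  typical package-check budgets.

## A worked example

```{r example}
sim <- simulate_preset("small", seed = 1)
res <- build_atlas(sim$config)
res$counts$totals

# one anatomical-structure population, with provenance
pop <- res$aspop[["female|azimuth|AS1"]]
pop
attr(pop, "datasets")
```

The recovered population equals the sum of the generator's realized
per-dataset counts exactly, because the sites are fully contained
(intersection percentage 100). With straddling sites the package reproduces
the analytic intersection-weighted mixture to 1e-6, which the acceptance
suite asserts.
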