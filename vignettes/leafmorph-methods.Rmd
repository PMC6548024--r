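---
title: "Models and methods behind leafmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

leafmorph studies how two interacting growth modes shape leaves: an
organ-wide, differentiation-coupled growth mode, and a local, directional
mode driven by patterning of growth foci along the leaf margin.  Simple
leaves (serrated, as in *Arabidopsis thaliana*) and dissected leaves
(leaflet-bearing, as in *Cardamine hirsuta*) can be read as different
balances of these modes: global slowing and prolongation of growth
broadens and multiplies marginal protrusions, while local repression of
growth at protrusion bases (the RCO domain) turns serrations into stalked
leaflets.  The package provides three computational pillars — a 1D
geometric margin simulator, a 2D growing-tissue model, and cell-resolution
growth quantification — plus a synthetic data generator that makes every
quantification step testable against known ground truth.

# The geometric margin model

The margin is a one-dimensional sequence of material sample points, each
carrying arc position, lateral outgrowth displacement, CUC2 competence,
convergence-point and differentiation flags, and a local growth-repression
factor.

**Growth.**  Each inter-point segment extends multiplicatively,
`L <- L * exp(g * grad(arc) * repression * diffFactor * dt)`.  The
basipetal gradient `grad` is piecewise linear: 1 at the base, declining to
`gradientFloor` at the growth-zone boundary (`growthZone`, um), constant
beyond.  A differentiation line recedes from the distal end at constant
speed in normalized arc coordinates (`diffSpeed`, 1/day); differentiated
material grows at the reduced factor `diffFactor`.  Both choices are the
simplest forms consistent with a basipetally graded, differentiation-
limited margin; nothing in the behaviour we test depends on the precise
functional form of the gradient.

**Patterning.**  Margin patterning is growth-driven: any maximal competent,
non-differentiated interval whose arc length exceeds `LThresh` is broken
by an auxin convergence point at its midpoint (midpoint placement is
parameter-free and symmetric; simultaneous qualifying intervals are
processed proximal to distal).  A non-competent gap of width `cpGap`
opens around the new point, so patterning is self-limiting and
convergence points keep a minimal spacing.

**Outgrowth.**  At insertion, a Gaussian kernel of half-width `wOut`
assigns each margin point a *material* outgrowth competence (its value is
advected with the point and interpolated on resampling).  Points then
gain lateral displacement at rate
`vOut * competence * grad(arc) * diffFactor`.  Treating outgrowth
competence as a material property, and modulating outgrowth by the same
basipetal gradient as longitudinal growth, matters: it makes protrusions
objects that grow with the margin, so extending the growth zone enlarges
protrusions without changing their shape, while increasing longitudinal
growth smooths them — the two antagonistic knobs the morphospace sweeps
exercise.

**Basal repression (RCO).**  At convergence-point insertion a boxcar
repression profile is attached to the flanking material:
`flank_only` represses the two flanks at arc distance
(`cpGap/2`, `cpGap/2 + rcoExtent`] from the point;
`extend_into_base` extends the repressed zone three times deeper into the
protrusion base.  Repression multiplies longitudinal growth by
`1 - rcoStrength`; outgrowth is unaffected.  A narrow flank zone trims
the basal width of a protrusion; the extended zone freezes most of its
flank material, which therefore climbs almost vertically in the
silhouette — a stalk.

**Silhouette and the planar lift.**  The primary silhouette is the
(arc, offset) curve.  Because arc length and offset evolve independently,
we also emit a planar lift with `dx = sqrt(dL^2 - dOffset^2)` per segment
(clamped at a small positive fraction of `dL`), which preserves arc
length and renders frozen, steeply-climbing material as near-vertical
outline segments.  The lift is x-monotone by construction, so outlines
cannot overhang; a petiolate form is therefore detected not as a bulge
but as a long near-constant-width band: the `stalked` flag requires a
contiguous band covering at least 40% of the protrusion height whose
width varies by less than 10% and stays below half of the basal width.
Protrusion triangle metrics (base width between flanking sinuses, height
of the tip over the base chord, asymmetry as the difference of the two
edge lengths) are computed on the lift.

**Defaults.**  The wild-type reference (`marginParams()`) uses an initial
margin of 100 um sampled at 60 points from 2 to 7 DAI at `dt = 0.02` day,
`gLong = 0.45`/day, a 160 um growth zone with floor 0.08, `LThresh = 45`
um, `vOut = 18` um/day with `wOut = 12` um, and no repression.  These
values were chosen once to give a margin a few hundred um long bearing a
handful of serrations with a proximodistal size gradient, the regime the
morphospace exploration starts from.  Resampling inserts midpoints
wherever spacing exceeds twice the initial spacing; inserted points
interpolate continuous attributes linearly and combine flags
conservatively (a segment is differentiated only if both parents are).
The model is fully deterministic; the seed is recorded only for
provenance.

# The growing-tissue model

The 2D tissue model implements a specified-versus-resultant growth
architecture on a triangulated primordium: per-triangle *specified*
growth tensors update per-triangle rest shapes; elastic relaxation of the
connected tissue then produces the *resultant* deformation, which can
differ locally from what was specified wherever neighbouring
specifications conflict.

**Mesh.**  The initial primordium at 1 DAI is a hexagonal disk
triangulation (ring k carries 6k vertices, so element quality is uniform
and no vertex has excessive valence — a property the anisotropic growth
below depends on) mapped to a rounded oblong 40 um long and 24 um wide,
base at y = 0.  Tissue labels: triangles with two boundary vertices form
the one-triangle-deep margin strip; a central proximal strip (30% of the
half-width, lower 55% of the length) is midrib/petiole; the rest is
blade.

**Specified growth.**  During the initiation window (1–1.85 DAI) growth
is homogeneous and anisotropic along the organ axis (0.85/day along,
0.30/day across).  Afterwards the blade grows isotropically (0.55/day),
the midrib/petiole anisotropically (0.78/day along, 0.05/day across) with
its axis taken from the local gradient of the differentiation factor (a
direction that is always defined and follows organ shape), and margin
elements respond to the reaction state: elements at an auxin maximum or
its immediate chain neighbours receive a boosted (×1.8), outward-oriented
anisotropic tensor (spreading the protrusion deformation over several
elements); CUC2 growth inhibition (×0.35) is sinus-local — it acts at the
auxin minimum between each pair of adjacent maxima, plus immediate
neighbours, where CUC2 stays high, and with `cucRadius = 1` reaches one
element deep into the adjacent tissue.  Inhibiting the entire high-CUC2
margin instead would wrap the organ in a slow-growing ring and crush the
interior, which is neither observed nor intended.  Differentiated
elements are scaled by 0.12.

**Differentiation factor.**  A factor produced at the leaf base (Dirichlet
source on basal vertices) diffuses (P1 finite elements, implicit step)
and decays; its penetration length is `sqrt(D/k) = 250` um with the
default `D = 2e5` um²/day, `k = 3.2`/day.  Once the organ outgrows this
length, distal elements fall below the threshold `cStar = 0.30` and
differentiate irreversibly — a differentiation front that recedes
basipetally in relative coordinates.  At margin auxin maxima the
effective level is reduced by 35% (auxin accelerates differentiation);
the alternative of raising the local threshold is equivalent at this
level of description.

**Margin reaction.**  Margin cells (the ordered boundary chain) carry
auxin, CUC2 and PIN1 allocation; the seed perturbation of auxin is
mirror-symmetric about the midline, since leaf primordia pattern their
margins in near-symmetric left/right pairs and an asymmetric seed makes
the simulated organ bend.  PIN1 allocates between the two
neighbours proportionally to neighbour auxin to the power `hExp = 2`,
transport flux is `transportCoef * cuc * allocation * auxin` (the CUC2
scaling implements the requirement of CUC2 for maxima organization),
auxin is produced and decays linearly and exchanges passively between
neighbours, and CUC2 decays where auxin is high (Hill threshold
`auxinThr`) and recovers elsewhere.  Differentiated cells drop out.
From a uniformly perturbed state this produces interspersed auxin maxima
and high-CUC2 intervals, with the auxin rise at each nascent maximum
preceding the local elimination of CUC2 — the event ordering that
distinguishes this mechanism from oscillatory or CUC2-first alternatives.

**Elastic relaxation.**  The published tissue mechanics is a
finite-element formulation; here we use a 2D plane corotational
linear-elastic analogue (constant-strain triangles, uniform modulus,
Poisson ratio 0.3): with per-triangle polar rotations held fixed the
energy is quadratic, so relaxation alternates rotation updates with one
sparse SPD solve, pinning only rigid-body modes.  Elements that are transiently degenerate
or inverted during the iteration reuse their previous rotation (the
quadratic energy then pulls them back); the inversion check applies to
the final relaxed configuration.  Two further regularizations keep
strongly incompatible growth tractable: plastic yielding (an element
whose elastic area mismatch exceeds roughly a factor of two remodels its
rest shape to the realized one, provided that shape is well-conditioned
— wall stress relaxation, in tissue terms), and local untangling (the
vertices of a rarely occurring folded element are moved to their
one-ring average and the tissue re-relaxed).  All in-scope claims
concern in-plane shape, for which this analogue suffices; out-of-plane
buckling and 3D curvature are out of scope.  Compatible growth (uniform
isotropic specification) relaxes to the exact uniform scaling, which the
tests assert to 0.1%.

**Remeshing.**  Edges longer than `remeshFactor` times the initial mean
boundary edge length (scaled by the square root of organ elongation, so
element count tracks organ size sublinearly) are bisected — boundary
edges to refine the margin as it extends, interior edges to prevent
sliver elements under strong midrib anisotropy.  Rest shapes are split
exactly in rest coordinates; margin-cell attributes of an inserted
boundary vertex are interpolated from its neighbours.

**Calibration.**  The default configuration is calibrated so the
simulated wild-type midline measures about 150 um at 3 DAI and about
800 um at 7 DAI, the organ lengths at which simple and dissected leaves
are compared stage-for-stage (the defaults give 155 and 761 um with the
default seed).  The calibration fixes the initiation-window rate, the
post-initiation blade/midrib rates and the differentiation threshold
jointly; all other reaction and mechanics parameters were set by the
qualitative behaviours described above and left untouched by the
calibration.  The midline is measured as the arc length of the polyline
of band midpoints along the principal axis (20 bands), a robust stand-in
for the outline medial axis on these shapes.

**Problem sizes.**  The default runs use a 150-triangle initial mesh
growing to roughly 1700 triangles by 7 DAI, 300 growth steps of 0.02 day
with 10 reaction substeps each; one full simulation takes about 90
seconds on one CPU, and the test suite reuses one wild-type and one
ablated run across test files.

# Cell-resolution growth quantification

Quantification consumes segmented tessellations (shared junction table +
per-cell vertex cycles) and daily child-to-parent lineage maps, the data
regime produced by confocal time-lapse segmentation pipelines.

* **Area extension**: per reference cell,
  `100 * (sum of daughter areas - parent area) / parent area`.
* **Growth anisotropy**: the best-fit affine deformation of the cell's
  junctions (matched by vertex id across time points) is decomposed by
  SVD; we report `ratio = kmax/kmin`, `pct = 100 * (1 - kmin/kmax)` and
  the orientation of the major stretch in degrees in [0, 180).  The
  percentage definition is stated explicitly because display rules such
  as "anisotropy > 40%" depend on it; the ratio is always reported
  alongside so users can re-threshold.  Cells with fewer than three
  non-collinear matched junctions are flagged, never silently dropped.
* **Lobeyness**: cell perimeter divided by convex-hull perimeter
  (exactly 1 for convex cells), the standard pavement-cell waviness
  metric.
* **Lineage algebra**: daily maps compose by functional composition;
  composition equals brute-force path following (a property test checks
  this over random division forests).
* **Alignment graphs**: reference-time cells are ordered along the
  proximodistal axis (arc distance along the banded midline, or hop
  count through the adjacency graph in cell-number mode) and split into
  equal-count bins (default 10, i.e. each bin holds 10% of
  reference-time cells); per bin we report mean and SEM of area
  extension or proliferation, or the percentage of final tissue area
  descended from the bin (contribution mode, bins summing to 100).  SEM
  pools cells within a bin of one sample; pooling biological replicates
  instead is a flag away, since published figure legends do not resolve
  which convention their per-bin n refers to.
* **Region classification** follows the fate-mapping recipe: label at
  the final time, pull back through lineage, mark sinuses, push forward.
  Because division planes reset per-cell elongation, the elongation
  criterion (aspect ratio > 2.5, proliferation at or below the median)
  is evaluated on each reference cell's *clone outline* — the merged
  boundary of its descendants — which is also what lineage-tracing
  panels display.  Sinus cells are the margin-adjacent reference cells
  in the slowest-growth decile lying between protrusion tips detected on
  the final outline; with no protrusions there are no sinus cells.
* **Protrusion triangles**: base width (distance between flanking
  sinuses), length (tip height over the base chord) and asymmetry
  (difference of edge lengths), with landmarks supplied or auto-detected
  from the smoothed outline curvature.

# The synthetic time-lapse generator

The generator emulates the study's data regime so that every
quantification stage can be validated without any imaging data: a
leaf-shaped domain (petiole strip plus half-elliptic blade, a few hundred
um long) tiled by a centroidal Voronoi tessellation of 100–1500 cells;
daily observations; programmed growth fields of a few tens of percent per
day (uniform; basipetal with a receding proximal zone; or tissue-type
with an anisotropic central strip); size-triggered divisions by the
shortest wall through the centroid with orientation jitter (a standard
plant-cell division proxy); and Gaussian junction jitter (default
0.25 um, the scale of segmentation uncertainty) applied only after
ground truth is recorded.  The noise bound the tests assert (median
apparent anisotropy of truly isotropic cells below 5% at 0.5 um jitter on
both observations) holds at the generator's epidermal cell scale of
roughly 25 um; proportionally smaller cells carry proportionally more
apparent anisotropy.

Junctions move through the programmed field as follows: uniform fields
apply the exact global map; the basipetal field integrates its stretch
along the axis so the local strain matches the programmed rate
pointwise; the tissue field applies each cell's local affine and
averages predictions at shared junctions.  The averaging makes region
cores deform exactly by their programmed tensor but blurs the field over
one cell at region interfaces — interface cells genuinely grow an
intermediate tensor, which is why ground-truth comparisons of region
labels are evaluated on interface-excluded cells.  What passing these
tests shows about real data is therefore bounded: the pipeline recovers
growth fields faithfully where segmentation is correct and deformations
are locally affine; it says nothing about segmentation error, 3D surface
curvature, or fluorescence quantification, none of which the generator
emulates.

# Numerical choices and degenerate inputs

Time steps: margin `dt = 0.02` day (a convergence check against halved
steps is part of the test suite's closed-form growth tests); tissue
growth step 0.02 day with 10 reaction substeps; diffusion solved
implicitly so the factor field is stable at any step.  Relaxation stops
when the relative vertex displacement per corotational iteration falls
below 1e-8 (at most 12 iterations; inverted elements abort with the
element id).  Voronoi vertices are snapped to a 1e-6 um grid to build the
shared junction table.  Degenerate inputs fail loudly: empty competence
zones yield no patterning, polygons with fewer than three vertices,
self-intersecting cells, duplicate ids, missing vertex references and
broken lineage chains all raise errors naming the offending entity.

# Known limitations

The margin model has no mechanical coupling along the margin and no
stochasticity; protrusion overhangs cannot be represented in its planar
lift.  The tissue model is 2D plane elasticity: no buckling, no
cell-level mechanics, and its published finite-element counterpart is not
reproduced in detail — only its stated qualitative behaviours and the
organ-length calibration.  RCO-type repression is explored in the margin
model only.  The quantification assumes planar tessellations with
junction identity across time points; curved-surface corrections are out
of scope.
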