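---
title: "Methods: image-based leaf-angle and shoot-growth phenotyping in grapevine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based leaf-angle and shoot-growth phenotyping in grapevine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovine)
```

## The problem

Grapevine leaves reorient under water deficit: as midday stem water
potential ($\Psi$, MPa) falls from about $-0.4$ (well-watered) towards
$-1.1$ MPa (severe stress), leaves droop, and the leaf angle rises from
roughly 75° to roughly 110°. Leaf angle is therefore a candidate
non-invasive proxy for drought stress — provided it can be measured from
images instead of by hand with a goniometer. `phenovine` implements the
computational side of such a phenotyping protocol:

1. **3D leaf angles** from a colored point cloud of a potted plant
   (as produced by multi-view structure-from-motion): color-based noise
   removal, region-growing organ segmentation, total-least-squares blade
   and petiole fits, and the angle itself.
2. **2D RGB indices** from one top view (TV) and three side views (SV at
   0°, 45°, 90°): the projected shoot area
   $PSA = N_{0°SV} + N_{45°SV} + N_{90°SV} + 0.3\,N_{TV}$ (pixels) and the
   greener fraction (GGF), the share of plant pixels with HSI hue strictly
   between 80° and 180°.
3. A **linear leaf-area calibration** $LA' = a \cdot PSA + b$ with pooled
   k-fold cross-validation.
4. A **synthetic-plant generator** that produces every input with known
   ground truth, so the whole pipeline is testable end to end without any
   imaging hardware.

## The leaf-angle model

Leaf angle is defined as the *supplement* of the deviation of the leaf
midrib from the petiole direction: a blade continuing its petiole has
angle 180°, a fully folded-back blade 0°, and drought moves grapevine
leaves from ~75° up past 90°. Per leaf we fit

- the **blade plane** by total least squares (centroid plus the
  eigenvector of the smallest eigenvalue of the position covariance), and
- the **petiole line** by the principal axis (largest eigenvalue), oriented
  proximal→distal.

The midrib itself is not fitted. Its direction is reconstructed as the
unit projection of the junction→blade-centroid vector onto the blade
plane. For any planar blade whose midrib runs through the blade centre
this proxy is exact, and it is well defined whenever the centroid does not
sit on the plane normal through the junction (that degenerate case raises
an explicit error). With deviation
$\theta = \arccos(d_{petiole} \cdot m)$ the reported angle is
$180° - \theta$.

Numerical conventions: plane normals are sign-fixed (non-negative z, ties
towards non-negative x then y); the petiole's principal-axis sign ambiguity
is resolved by a junction hint; $\arccos$ arguments are clamped to
$[-1, 1]$.

### Robustness at organ junctions

Automatic segmentation inevitably leaves a few points of the stem attached
to a petiole region (and occasionally blade points at the petiole tip).
Those points lie far off the fitted primitive and would tilt it by several
degrees. `plant_leaf_angles()` therefore applies a short trimmed
reweighting loop to both fits: points whose orthogonal residual exceeds
three times the median residual are dropped and the fit repeated (at most
three passes, never below half the points). On clean organs the loop is a
no-op; with contamination it restores noise-free angle errors to below
0.01°.

## Point-cloud cleaning and segmentation

**Noise filter.** A point is removed iff $r+g+b \le 70$ (too dark for leaf
tissue) **or** $g \le b$ (blue-dominant sky/pot reflections). Either
condition suffices. The green/blue ratio test $g/b \le 1$ is implemented
as the integer comparison $g \le b$, which avoids division and settles the
$b = 0$ cases consistently with the ratio's limit ($g=0, b=0$: removed;
$g>0, b=0$: kept). The filter is a pure per-point predicate — idempotent,
order-preserving, and checked in the tests against an independent
per-point brute-force evaluation.

**Region growing.** Organs are recovered as smooth connected regions over
a fixed-radius neighbour graph. Every point gets a local PCA over its k
nearest neighbours; the eigenvalue spectrum classifies its neighbourhood
as *surface-like* ($\lambda_2/\lambda_1 \ge 0.25$) or *line-like*. Growth
starts at the unvisited point of lowest curvature (ties by index, so the
procedure is deterministic) and joins a neighbour when its shape class
matches and its local direction agrees within the angle threshold —
normals for surfaces, tangents for line-like points. Line-like structures
(petioles, stem) have no stable normal, and tangent coherence is what
keeps the vertical stem from merging with the horizontal petioles it
touches. Points left over at boundaries and corners, where small-sample
PCA is unstable, are absorbed by the nearest region within the connection
radius. Defaults (k = 12 neighbours, 20° angle threshold, connection
radius 6 length units, minimum region size 15) suit the default synthetic
plant's sampling density; all are exposed via `region_growing_params()`.

**Organ classification.** Each region's covariance spectrum
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ decides its anatomy:
$\lambda_2/\lambda_1 < 0.15$ marks a line-like region (petiole or stem),
otherwise $\lambda_3/\lambda_2 < 0.2$ marks a blade. Near-vertical
line-like regions whose union spans most of the height range form the
stem. Each remaining petiole candidate is paired greedily with the blade
nearest either of its axis endpoints (the matched endpoint becomes the
junction estimate); blades left unpaired within the pairing distance are
flagged `petiole_missing` and excluded from angle computation but counted
in the reported yield — mirroring the fact that real reconstructions
recover only a subset (roughly 3–15 of 20–25) of the leaves present.
Supplying per-leaf seed points restricts and orders the leaves
("semi-automatic" mode); the fully automatic mode is the default and is
what all tests exercise.

**Hole filling.** `fill_small_holes()` voxelises a region and adds one
synthetic point at the centre of each empty voxel that belongs to a small
interior empty component (not reaching the grid boundary in any
non-degenerate dimension) and has at least 4 of 6 face neighbours
occupied. It never removes points. The synthetic generator produces
gap-free organs at the default densities, so the pipeline leaves hole
filling off by default; it exists for sparser real reconstructions.

Whether hole filling should precede or follow segmentation, and whether
stem points were excluded before leaf analysis, are not fixed by the
protocol this package follows; here hole filling is optional and the stem
is segmented explicitly so it can never leak into blade fits.

## RGB indices

Images are 8-bit RGB arrays. Plant pixels are segmented by maximum
channel distance to a uniform background color — a deliberately simple
stand-in for proprietary platform segmentation, and exact on rendered
synthetic views. Hue uses the classical arccos HSI formulation (among the
several published HSI variants) with $H := 360° - H$ when $b > g$;
achromatic pixels ($S = 0$ or zero denominator) carry an explicit
undefined-hue flag rather than a fabricated value. GGF counts plant
pixels with hue *strictly* inside (80°, 180°) over all plant pixels;
undefined-hue pixels count in the denominator only. Two conventions are
configurable because the protocol leaves them open; the defaults are:
the denominator is the segmented plant (GGF values near 0.6–0.7 in
published trajectories are only consistent with a plant-pixel
denominator, not a full-frame one), and side views are aggregated by
pooling pixels across the three SVs rather than averaging per-view
fractions.

PSA is the exact weighted count above; no pixel→cm² calibration is
attempted, because the published calibration slope implies a rescaled PSA
unit that is not recoverable from the available information. The
calibration is treated as unit-agnostic.

## Leaf-area calibration

`fit_la_model()` implements OLS from the closed form
(slope $= \mathrm{cov}/\mathrm{var}$), with $R^2 = 1 - SSE/SST$
(defined as 0 when $SST = 0$). `kfold_cv()` shuffles once under a seed,
splits into k contiguous folds of size $\lfloor n/k \rfloor$ or
$\lceil n/k \rceil$, predicts every row exactly once out-of-fold and pools:
$R^2_{CV} = 1 - SSE_{pooled}/SST_{pooled}$. Pooling is used instead of
averaging per-fold $R^2$ because per-fold values degenerate at fold sizes
of 2–4 observations. The fitted object is a classed S3 model with
`print`, `summary`, `coef`, `predict` and `residuals` methods and JSON
persistence.

## The synthetic generator: what it emulates, what it does not

`generate_plant_cloud()` builds a vertical stem, straight petioles leaving
the stem at their nodes (horizontal by default, with an optional insertion
tilt), and planar disc blades of radius $R$ whose midrib makes the
configured angle with the petiole; the disc centre sits one radius along
the midrib from the petiole tip, so the junction lies on the rim and the
in-plane junction→centroid direction *is* the midrib. Plant points are
colored green-dominant (always passing the noise filter), jittered
isotropically, and the bounding volume is peppered with dark and
blue-dominant clutter that exactly matches the removal criterion. Truth
records per-point labels, per-leaf generating vectors, angles, and the
canopy region by node index (nodes 1–5 lower, 6–11 middle, above 11
upper).

Key default conditions, chosen once:

- leaf angles span 75–110° (the observed well-watered → stressed range);
- position jitter sd 0.7 length units = 2% of the default blade radius
  (the scale at which angle recovery is still required to hold);
- azimuths follow a 137.5° phyllotactic spiral so leaves do not overlap;
- the $\Psi$→angle link defaults to slope $-50$ deg/MPa, intercept 55°,
  which maps $\Psi \in [-1.1, -0.4]$ onto angles 75–110°. Published work
  reports only the strength of this relation ($R^2$), not its
  coefficients, so the link is an explicit, configurable modelling choice,
  not a literature value.

The generator deliberately does **not** emulate: lobed or serrated
vine-leaf outlines (a plane plus an in-plane midrib is all the angle
mathematics uses; an optional out-of-plane curvature parameter exists to
stress the plane fit), perspective imaging (orthographic projection keeps
the pixel-count truth exact), structure-from-motion error structure
(occlusion, ghost points, density gradients), or photorealistic color.
Consequently, passing tests demonstrate the correctness of the
*computations* under controlled geometry — not that a particular real
camera rig will reach the same angle yield or accuracy on real vines.
The observed 15–35° systematic offset between goniometer and 3D angles in
field data is likewise out of scope: it stems from unknown details of the
original 3D angle convention, and no attempt is made to reproduce it.

## The simulated experiment

`run_experiment()` wires everything together over a configurable design —
by default 3 irrigation treatments (restoring 100%, 60% and 30% of soil
available water capacity) × 3 plants × 4 days, with per-treatment $\Psi$
trajectories spanning $-0.4$ to $-1.1$ MPa. Per plant-day: generate at
link-implied angles → filter → region growing → organ classification →
leaf angles → render views → masks, GGF, PSA → predicted leaf area. A
final OLS of recovered mean angle on $\Psi$ closes the loop; with all
noise sources off the recovered slope matches the configured link to
within 0.01% in the bundled configuration. Every plant-day derives its
own sub-seed from the experiment seed, so runs are bit-reproducible; a
failing plant-day flags its row instead of aborting the run.

Problem sizes used throughout the tests — plants of 5–8 leaves at about
2,500–3,700 points, 500 calibration pairs, a 36-plant-day demo experiment,
and 50-leaf angle-recovery batches — are small enough to run in seconds to
a few minutes on a single core while still exercising every code path at
the documented noise conditions.

## Known limitations

- Region growing assumes organs are separated by more than the connection
  radius; overlapping or touching blades merge and fail the planarity
  test, lowering yield (as in real reconstructions, where only a subset of
  leaves is recoverable — the package reports this as a yield fraction
  rather than failing).
- The brute-force neighbour search is $O(N^2)$ in chunks; fine for clouds
  up to a few tens of thousands of points, not for full-resolution
  photogrammetric scans (downsample first).
- Canopy-region tagging without node information falls back to height
  terciles of petiole junctions, which need not match true node counts on
  irregular plants.
- The GGF denominator and side-view pooling conventions are choices
  (documented above) where the protocol is ambiguous; both are
  configurable.
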