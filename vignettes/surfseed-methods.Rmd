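---
title: "Surface-seeded tractography: models, parameters and design notes"
author: "surfseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-seeded tractography: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Relating motor impairment to the microstructure of specific white-matter
pathways requires three things to line up in each individual: where the
functionally relevant cortex is (task fMRI), which streamlines belong to
which pathway (tractography plus classification), and a per-tract
microstructure summary that can be compared across hemispheres
(FA/MD asymmetry).  In cohorts with significant brain pathology - for
example children with unilateral cerebral palsy - every one of those
steps is fragile: heads move, lesions distort anatomy, and atlas-driven
shortcuts fail.  `surfseed` implements a surface-based pipeline built
around the grey-matter/white-matter interface mesh: the fMRI statistics
are computed *on* the mesh, streamline seeding starts *from* the mesh,
and the same mesh acts as the anatomical constraint for tracking.

This vignette records the models, the tunable parameters, and the design
decisions a maintainer would want to know, in the order the pipeline
runs.

# Interface mesh

`cleanWMSegmentation()` applies a conservative cleanup before meshing:
the inverted brain mask is dilated three times with a full 3x3x3
structuring element, and any 26-connected white-matter cluster that both
touches this rim and is smaller than 40 voxels is relabelled grey
matter.  Only WM-to-GM changes are possible, so the brain mask is
conserved.  26-connectivity is the most permissive choice and removes
the most spurious islands; the island-size threshold (40 voxels) and the
dilation count (3) are exposed as arguments.

`extractInterfaceMesh()` triangulates the 0.5 isosurface of the (lightly
smoothed, trilinearly resampled) WM indicator.  We decompose each
sampling cell into six tetrahedra and polygonise per tetrahedron rather
than using the classical 256-case cube tables: the output class is the
same (closed, watertight, consistently oriented), each tetrahedral case
is derivable in a few lines instead of a transcription-error-prone
table, and orientation can be fixed robustly per triangle against the
local field gradient (normals point from white into grey matter).  The
sampling grid spacing is adapted (up to three extractions) so the mean
vertex-to-neighbour distance lands within about 20% of the requested
`spacing` (default 0.9 mm); ten Taubin lambda/mu iterations
(0.5 / -0.53) regularise triangle shape with negligible shrinkage - on a
20 mm ball phantom the surface area lands within a few percent of
4*pi*r^2 and all vertices within a voxel diagonal of the true sphere.

`decimateMesh()` (default fraction 0.5, i.e. halving) collapses shortest
edges to their midpoints, with a link-condition test to preserve
manifoldness and a normal-flip test to preserve orientation.  Quadric
error metrics would give slightly better shapes; midpoint collapse of
*short* edges already meets the package's accuracy contract (Hausdorff
deviation below 1.5x the source mean edge, area error below 5% on the
ball phantom) with far less machinery, which is why it was chosen.

`offsetMesh()` displaces vertices along area-weighted vertex normals:
+1 mm before EPI sampling (to read grey matter), -1 mm before seeding
(to start tracks in white matter).  Self-intersection is permitted and
not repaired - at 1 mm offsets on brain-like geometry it is confined to
thin sulcal fundi and has no effect on the downstream statistics.

All meshes and streamlines live in world millimetres (RAS); voxel access
goes through the inverse affine with 0-based indices and voxel-centre
convention.  That convention is stated once here and used everywhere.

# Surface fMRI

**Motion.** Framewise displacement is the Power sum: absolute
frame-to-frame differentials of the three translations plus the three
rotations converted to arc length at a 50 mm head radius.  Frames with
FD above 0.9 mm are censored; datasets with 20 or more censored frames
across the session's two scans are rejected outright (an explicit
dataset-rejection outcome, not an error).  The boundary is sharp: 19
censored frames pass, 20 reject.

**Projection.** Each vertex reads the nearest EPI voxel at its +1 mm
offset position, per frame.  Vertices outside the field of view carry NA
and are excluded from the GLM.

**Smoothing.** `smoothOnSurface()` integrates the heat equation on the
mesh with the cotangent Laplace-Beltrami operator (negative weights
clamped at zero) and lumped vertex-area masses, using backward-Euler
substeps (20 by default - unconditionally stable).  Total diffusion time
is t = FWHM^2 / (16 ln 2), the planar-Gaussian equivalence.  Two exact
properties follow from the discretisation: constants pass through
unchanged, and the surface integral (area-weighted mean) is conserved to
machine precision.  On a flat 1 mm grid the empirical kernel is
Gaussian with FWHM within a few percent of nominal (half-max profile
readings sit slightly low, near 7.3 mm for a nominal 8, because the
discrete impulse elevates the peak; a Gaussian fit of log-value against
squared radius reads 8.0).  The reason for surface smoothing at all is
specificity: on a folded sheet with banks 2 mm apart in space but tens
of millimetres apart along the surface, leakage across the sulcus is
below 1% of the peak, where an 8 mm volumetric kernel would carry over
more than half.

**Design.** The task regressor is the move/stop boxcar (nine 30 s
alternating blocks, TR 3 s by default) convolved with the canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32 s support),
built on a 0.1 s grid and sampled at the actual frame times, so nothing
assumes even temporal spacing.  Covariates: the three rotation
parameters only (translations are deliberately excluded), a
discrete-cosine high-pass set for a 120 s cutoff
(floor(2T/cutoff) columns), and an intercept.  Censored rows are
deleted, never interpolated; a fit after censoring is identical to a fit
on a dataset that never contained those frames.

**GLM.** Per-vertex OLS with AR(1) prewhitening using one pooled
coefficient.  The naive residual lag-1 correlation is biased because the
projection absorbs autocorrelation (the high-pass set especially), so
the coefficient is estimated by moment matching: solve
tr(RAR V(rho)) / tr(R V(rho)) = observed residual lag-1, with R the
residual-forming matrix and A the symmetrised lag-1 operator.  On AR(1)
noise with rho = 0.3 this recovers the coefficient to within a few
hundredths and the uncorrected per-vertex type-I error sits inside the
binomial confidence band of 0.05.  Degrees of freedom are n - p with the
pooled coefficient treated as known - defensible because it is estimated
from thousands of vertices.

**Thresholding.** Family-wise error control is Bonferroni across tested
vertices.  The original analysis ported volumetric FWE machinery to the
mesh without stating the surface correction; Bonferroni is deterministic,
conservative and exactly testable by simulation, which is why it is the
package's choice.  Components of the thresholded mask smaller than 3
vertices are discarded; remaining components are kept by id or by
nearest-point selection (ordering: size descending, then lowest vertex
index).  The two scans' masks (able and impaired hand tasks) are
OR-combined into the seeding mask.

# Tractography

Seeding is area-proportional over the triangles whose three vertices all
survive thresholding, with uniform square-root barycentric placement
inside each chosen triangle; the initial direction is the inward
triangle normal.  Propagation is fixed-step (0.2 mm) with a minimum
curvature radius of 1 mm, enforced as a hard bound on the turning angle
per step, theta_max = 2 asin(step / (2 r_min)) = 11.48 degrees; for
probabilistic fields up to 50 redraws are allowed before termination
(a deterministic field that returns the same direction twice stops
redrawing immediately).  The bound applies from the second step on: the
seed direction is a surface normal, not a field sample, so the first
step is only sign-aligned to it.  Tracks terminate on: entering a voxel
with FA at or below 0.1 (that node is kept - the track "enters" the
voxel); a step segment crossing any triangle of the constraining mesh
(the crossing point is not kept); the field returning no direction;
reaching the brainstem termination plane; or 250 mm of length.
Segment-triangle tests are vectorised Moller-Trumbore against the whole
constraint mesh.

Accepted tracks must pass through the thalamus or PLIC planar ROI, end
in the brainstem ROI, and never touch the corpus-callosum exclusion ROI.
ROI membership is nearest-voxel per node - at 0.2 mm steps against >= 1
mm voxels a segment cannot skip a voxel, so no supercover test is
needed.  The 2D brainstem ROI acts as a termination plane ("terminated
in the brainstem ROI"): once a node's nearest voxel enters it, tracking
stops with that node kept, which is what makes "final node inside the
ROI" well defined for a 2D region.  Generation repeats
seed-propagate-filter until the target count (protocol: 20000; the test
phantoms use tens) or the attempt budget (100x target by default) is
exhausted; zero accepted tracks is a first-class "no tracks found"
outcome - in the clinical setting that is the signal of ipsilateral
organisation, not a crash.

Fibre orientation estimation is out of scope by design: any
`function(position, previousDirection)` returning a unit vector (or
nothing) plugs in.  The package ships a uniform field, a vector-volume
("peak") field with optional trilinear interpolation, a
centreline-following field, and a von Mises-Fisher jitter wrapper.  The
interpolated peak field exists because a nearest-voxel field is
piecewise constant: its direction jumps at voxel boundaries can exceed
theta_max and needlessly kill tracks under a 1 mm curvature radius.

# Two-stage track classification

Stage 1 (hemisphere split) uses four features per track - cortex-node X
and Y, midbrain-entry X and Y - and unweighted 2-means with
random-track initial means, three attempts, lowest global cost kept.
Clusters are named left/right by the sign of their mean midbrain X
against the midline (x = 0 in the common space, configurable).  Both
clusters landing on one side is legitimate (single-hemisphere input
yields one empty output).

Stage 2 separates corticomotor from thalamocortical tracks per
hemisphere with twelve features: midbrain-entry X, Y; X, Y, Z of the
node 50 nodes below the midbrain entry; X, Y, Z of the node 50 nodes
before the end; final-node X, Y; and 0/1 flags for PLIC and thalamus
passage (used literally, weight 1).  The cost is per-cluster weighted
squared error: thalamocortical weights all 1; corticomotor weights 0.49
on midbrain Y (the tract is elongated antero-posteriorly there - larger
spread is expected and should be forgiven) and 1.69 on the three
coordinates 50 nodes below the midbrain (the tract is spatially coherent
there - spread should be punished).  Initialisation: the thalamocortical
cluster starts from the track whose midbrain entry is nearest a point
5 cm posterior to the brain centre (mask centroid, -y in RAS); the
corticomotor cluster from the track farthest from that point among
tracks passing the medullary pyramids, defined as the anterior third of
the brainstem ROI in Y, falling back to the anterior third of terminal
nodes when no track qualifies, then to all tracks.  Ties break to the
lowest track index.  Twenty attempts are run; restarts draw random track
pairs but order each pair so the seed nearer the posterior point
initialises the unit-weight cluster - cluster identity is carried by the
weights, so initialisation must respect it for "which seed the cluster
descends from" to stay meaningful across restarts.  Convergence is zero
swaps or 1000 iterations; an attempt that empties a cluster restarts
from a fresh pair and still consumes its slot in the budget.  Tracks
shorter than 50 nodes beyond a reference clamp to the terminal node and
are flagged.  For very small problems `weightedKMeans(...,
exhaustivePairs = TRUE)` additionally restarts from every distinct pair,
which pins the exhaustive optimum in the package's oracle checks.

# Tract metrics

**Dispersion.** For each track, the stepping direction (the unit vector
of the segment leaving the interpolated position; the final segment at
100%) is evaluated at 20 arc-length fractions 0, 1/19, ..., 1.  At each
position the bundle's mean direction is the normalised arithmetic mean
of unit vectors, each track's deviation is the great-circle angle to
that mean, and dispersion is the mean squared deviation over positions
and tracks - radians squared.  The unit-vector mean is used instead of
separate circular means of inclination and azimuth because it has no
azimuth wrap-around pathologies and makes the statistic exactly
rotation-invariant; the spherical-coordinate variant (`mode =
"spherical"`) and node-index positioning (`byIndex = TRUE`) remain
available for comparison.  Interior directions are forward differences.
Exact anchors: identical parallel tracks give 0; two straight tracks at
90 degrees give (pi/4)^2 at every position.

**Superior/inferior split and sampling.** Tracks are cut at their first
node at or below the midbrain ROI's axial plane; node counts are
conserved.  FA/MD means are unweighted means over nodes
(nearest voxel); a unique-voxel weighting was considered and not
implemented - at 0.2 mm steps the node mean oversamples slow sections,
but both hemispheres are oversampled identically, and the downstream
quantity is a ratio.

**Asymmetry and correlation.** AI = (A - I)/(A + I) with A and I the
hemispheres opposite the able and impaired hands.  Age adjustment is OLS
residuals plus the grand mean (scale preserved; the adjustment method is
the package's choice - the source protocol names only "adjusted for
age"); correlation is squared Pearson with its two-sided p.

# Synthetic data

The generators are first-class, tested code and define the package's
study conditions.

`makeBrainPhantom()` builds a two-hemisphere label volume (ellipsoidal
GM, WM lobes split by a mid-sagittal gap, optional brainstem stalk so
the interface mesh does not seal the bottom - a real interface mesh is
open towards the spinal cord) with planted 10- and 39-voxel WM islands
at the brain edge for the cleanup rule.  `makeBlockEPI()` emulates the
acquisition: 90 frames at TR 3 s, nine 30 s alternating blocks, baseline
100, HRF-convolved activation injected around a geodesic surface patch,
stationary AR(1) noise (rho 0.3, matching the GLM's error model so the
calibration tests are meaningful), and an optional rigid motion script
applied per frame.  `makeBundles()` draws cubic Bezier centrelines per
tract class and hemisphere (corticomotor: lateral cortex, PLIC, anterior
brainstem; thalamocortical: cortex, thalamus slice, posterior
brainstem), resamples them at the tracking step size, jitters control
points per track (default SD 1.5 mm), and builds matched FA/MD corridor
volumes and the four planar ROIs.  The corticomotor jitter is
anisotropic - fanned at the cortex, elongated in Y at the capsule,
funnelled toward the pyramids - because that anatomy is exactly what the
stage-2 weights encode; with isotropic bundles the weighted cost cannot
tell the two classes' labellings apart and the classifier's naming
becomes a coin flip.  That also delimits what the tests show: they
validate the algorithm against geometry with the paper's assumed
structure, not against real dMRI noise, crossing fibres, or partial
voluming.  Default sizes: 50 tracks per bundle per hemisphere, 2 mm ROI
grids, FA 0.55 in corridors over 0.25 background, MD 0.8 over 1.0
(arbitrary 1e-3 mm^2/s units).  Lesions are per-hemisphere FA
reductions; a "severed" option zeroes a corridor band to reproduce the
no-tracks exit.  Every generator is a pure function of its arguments and
seed.

# Numerical choices and degenerate inputs

* Cotangent weights clamped at zero keep the smoothing system positive
  definite on poor triangles at a small cost in accuracy.
* Mean-direction normalisation fails only if opposing directions cancel
  exactly; that raises an error rather than returning a silent 0/0.
* Zero-length streamline segments are dropped with a warning before
  dispersion; fully degenerate tracks are an error.
* k-means assignment ties break to the lower cluster index;
  equidistant initialisation candidates break to the lowest track index.
* `asymmetryIndex` with A + I = 0 is an explicit error, not NaN.
* Tractogram float32 round-trips are byte-stable; a second write of a
  read file reproduces the first file exactly.

# Problem sizes in the shipped checks

The test-suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is statistically
meaningful: 200 random feature sets of up to 12 tracks for the
exhaustive clustering oracle; 10-20 bundle-phantom seeds (200 tracks
each) for label recovery; 4000 independent vertices for type-I
calibration and 1000 repetitions of a 40-vertex, 60-frame null for the
family-wise rate; 61x61 flat and 40 mm folded-sheet meshes for the
smoothing kernel; 25-40 accepted streamlines for the tracking-geometry
and end-to-end runs.  The full-protocol sizes (0.9 mm meshes, 20000
tracks) run through exactly the same code paths.

# Known limitations

* Bonferroni on the mesh is conservative relative to random-field or
  permutation corrections; a sign-flip permutation option is a natural
  extension and deliberately out of scope here.
* The decimation order follows mesh construction (decimate once, then
  project); the original description decimates after projection.  At
  halving on 0.9 mm meshes the difference is sub-voxel.
* The tracker is a pure-R reference implementation: correct and fully
  instrumented, comfortable at thousands of tracks, but not tuned for
  20000-track clinical batches on one core.
* Spatial normalisation to a template is reduced to an affine hook; the
  classification is documented as robust to coarse geometry, and the
  phantoms exercise exactly that robustness, but nonlinear warps are out
  of scope.
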