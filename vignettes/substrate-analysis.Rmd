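---
title: "Methods: structural substrate analysis of reentrant VT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural substrate analysis of reentrant VT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`vtsubstrate` implements an image-based analysis of the myocardial
substrate of re-entrant ventricular tachycardia (VT): late gadolinium
enhancement (LGE) CMR volumes are segmented into scar, heterogeneous
border-zone tissue (HT) and normal myocardium; wall thickness and
scar/HT transmurality are computed by a Laplace-equation field-line
method; thickness-gradient and distance maps are derived on the
endocardial surface; electroanatomic mapping points are co-registered to
the imaging mesh; lines of conduction block are detected in activation
maps; and the structural metrics at diastolic versus normal mapping
sites are compared with a nonparametric battery.

Because no suitable public animal dataset accompanies this kind of
study, every stage is validated against a synthetic phantom generator
with complete ground truth. The phantom is a first-class module: its
geometries (slab, spherical shell, truncated ellipsoid), scar patches of
controlled transmural fraction, HT rims, wall thinning, displaced
mapping frames and two-wavefront activation maps define exactly what the
package's tests can and cannot demonstrate.

# Tissue classification

Following the thresholding strategy used for electrophysiologically
relevant LV substrate, voxels inside the myocardial mask are classified
against the *maximum* signal intensity `M` within the mask:

* scar: `SI >= 0.60 M`
* HT: `0.40 M <= SI < 0.60 M`
* normal: otherwise.

Both boundaries are inclusive at the lower edge of their class, fixed
for determinism. The maximum is taken over the mask only, never the
whole image. No smoothing is applied before thresholding.

Max-referenced thresholds are fragile against the upper noise tail: a
single bright noise voxel shifts both cutoffs. On noisy phantoms this
manifests as isolated false-positive HT voxels scattered through normal
wall, which in turn corrupt *distance-to-HT* for remote points. The
optional `min_component` filter (off by default in `classify_tissue()`,
10 voxels in the pipeline default) removes scar/HT connected components
below a size threshold; this is the only cleanup performed.

The phantom's intensity model (normal 22, HT 42, scar 80 arbitrary
units, Gaussian noise sd 3) places each class mean inside its threshold
band with at least two noise standard deviations of margin for any
plausible in-mask maximum, so noiseless phantoms are recovered exactly
and noisy phantoms almost exactly after the component filter.

# Wall thickness and transmurality

The Laplace equation `div(grad u) = 0` is solved over the wall (the
union of normal myocardium, HT and scar) with Dirichlet conditions
`u = 0` at the endocardium and `u = 1` at the epicardium and zero-flux
conditions on untagged faces (e.g. the cut base of a truncated
ellipsoid). Surfaces are tagged by 6-connected face adjacency: wall
voxels touching blood are endocardial, those touching background
epicardial; a voxel touching both (a one-voxel wall) is assigned to the
endocardium with a warning.

Numerical choices, in order of consequence:

* **Sub-voxel boundary placement.** Imposing the Dirichlet values at
  tagged voxel centres biases both the potential and the traced
  thickness by about half a voxel per surface. Instead, each
  endocardial/epicardial interface is located as the 0.5-level of a
  Gaussian-smoothed binary phase indicator (sigma 0.8 voxels) and the
  condition is imposed at that sub-voxel position through a symmetric
  ghost-value (cut-cell) stencil: the ghost value is the linear
  extrapolation of the cell value through the boundary condition. The
  resulting system is symmetric positive definite and solved directly by
  sparse Cholesky; `tol` (default 1e-6) verifies the achieved residual.
  On a 20/30 mm spherical shell at 1.2 mm isotropic voxels the solution
  matches the analytic profile with mean absolute error ~0.006 and
  99th-percentile error ~0.016.
* **Known accuracy limit.** The maximum pointwise potential error on
  that shell is ~0.03, concentrated at the axis-pole caps of the
  voxelised spheres where the staircase surface is a flat plateau
  displaced by up to half a voxel from the true tangent plane. A
  per-face estimator cannot recover the surface position there — the
  information exists only at larger spatial scales — so pointwise
  potential values within ~1 voxel of a grid-tangent cap should be
  treated as accurate to ~0.03 rather than ~0.01. Thickness, an
  integral quantity, is essentially unaffected (median shell error
  < 0.1 mm).
* **Streamlines.** From each endocardial voxel centre, the normalised
  gradient of `u` (central differences, trilinear interpolation,
  NA-aware at the wall boundary) is integrated with fixed-step RK4
  (step = half a voxel) forward to the epicardial surface and backward
  to the endocardial surface, each surface again taken as the 0.5-level
  of its smoothed indicator with a 25-step bisection at the crossing.
  Wall thickness is the total arc length. Stagnating paths
  (`|grad u|` below 1e-8) are flagged undefined, never fabricated.
* **Transmurality.** Tissue labels are sampled by nearest voxel at
  equal arc-length intervals (segment midpoints and endpoints, i.e.
  quarter-voxel spacing); scar and HT transmurality are the label
  proportions along the path, so they approximate proportions of path
  length independent of integrator details. A node is *transmural* when
  scar% + HT% reaches 95%, the non-transmural cutoff used throughout.

On phantoms these choices give: slab thickness exact to the voxelised
width; shell (20/30 mm) median absolute thickness error < 0.1 mm;
patch transmural fractions 0.25–1.0 recovered within ~3 percentage
points (the residual is nearest-voxel quantisation at the scar
boundary).

# Surface metrics

The endocardial (or epicardial) surface is triangulated by marching
tetrahedra over the same smoothed indicator used by the solver, so mesh
and boundary conditions are mutually consistent; on the shell phantom
the mean vertex radius is within half a voxel and total area within a
few percent of the analytic sphere. (Marching tetrahedra was written
in-package; vertex welding at 1e-5 mm yields closed two-manifold
meshes on phantom geometries.)

Wall thickness at the vertices (transferred from the nearest endocardial
node) is interpolated with a polyharmonic cubic radial basis function
`phi(r) = r^3` plus a linear polynomial in ambient coordinates, and the
analytic gradient of the interpolant is projected onto each vertex's
tangent plane. Design notes:

* The polynomial term reproduces constants and linear ramps exactly,
  whatever the smoothing; on rank-deficient vertex configurations
  (planar test meshes) the dependent polynomial columns are dropped.
* `smoothing` (ridge on the kernel block, default 1e-2 of the mean
  kernel magnitude) suppresses the half-voxel ripple of measured
  thickness, which would otherwise generate spurious gradients of
  ~0.5 mm/mm; genuine border-zone gradients (several mm of thinning
  over a few mm) survive. Centres are subsampled above 2000 vertices.
* **Steep threshold.** There is no established quantitative definition
  of a "steep" thickness gradient; the package default is 0.5 mm/mm,
  configurable, with a quantile-based alternative
  (`quantile_threshold = 0.9`) reported alongside. Conclusions that
  depend on distance-to-steep-gradient inherit this choice.

Distances (to HT, to steep-gradient vertices) are Euclidean in world
millimetres — matching nearest-neighbour semantics — not geodesic along
the surface; the HT target set is all HT voxels anywhere in the wall,
not only endocardial ones.

# Co-registration

Mapping points are aligned to the imaging mesh in two stages: a
landmark (Kabsch/Procrustes) fit of paired fiducials — apex plus three
basal "ostial" landmarks, with reflection excluded and no scaling
(same-animal geometries; a similarity variant was deliberately not
implemented) — followed by iterative closest point refinement with
point-to-surface correspondences (exact foot point on the triangles
incident to the nearest vertex) and 10% trimming per iteration. An
iteration that would increase the trimmed RMS is rejected and the best
transform kept, so the reported RMS trace is non-increasing. Registered
points are assigned to the nearest mesh node within 1 mm (the
node-mapping radius), ties to the lowest node id; farther points stay
unassigned.

On noiseless phantoms, 100 random rigid perturbations (rotation up to
30 degrees, translation up to 10 mm) are recovered to point RMS
< 0.5 mm in at least 99 cases.

# Activation analysis

Conduction block is operationalised from its mapping definition — more
than 15 ms between adjacent activation points: an adjacency graph over
points within `neighbor_radius` (default 5 mm, the mapping-point density
scale) is thresholded on edge time differences; midpoints of
block-crossing edges are merged into chains (components of their
proximity graph); each chain is reduced to a centreline by averaging
midpoints in bins (default radius/2.5) along its principal axis, and the
block extent is the summed centreline arc length. Binning suppresses
the lateral scatter of crossing-edge midpoints, which would otherwise
double-count length through zigzag. An optional opposing-wavefront
filter (mean fitted time-gradients on the two sides differing by more
than 90 degrees) emulates the visual criterion that true block separates
wavefronts travelling in different directions; double-potential
detection is out of scope. On the two-front phantom (30 mm line, 40 ms
offset) the recovered length is within a few percent and exactly one
region is found; a uniform wavefront yields zero.

Note that across a genuine line of block the observed time difference
exceeds the nominal offset for separated point pairs (the detour time
accumulates), so the detected extent vanishes only when the threshold
exceeds the *maximum* adjacent gap, not the nominal offset.

Diastolic activation times are classified early/mid/late by equal
tertiles of the diastolic window (from QRS end), half-open at each
boundary for determinism; equal tertiles are a package convention, as
there is no standard definition of the phase boundaries.

# Statistics

Medians with interquartile ranges, Shapiro–Wilk normality, two-tailed
paired t, Mann–Whitney U (exact by enumeration when the pooled sample
is at most 16 without ties, mid-rank normal approximation with tie
correction otherwise), Kruskal–Wallis with tie correction, Dunn's (1964)
pairwise z on mean ranks with tie-corrected pooled variance and
Bonferroni-adjusted p-values (reported as adjusted), and Pearson
correlation. All base-R implementations are used where they exist;
Dunn's procedure is implemented here. Identical paired samples raise an
error (zero-variance differences) rather than returning t = 0.
Calibration: under the null at n = 30 per group, 10,000 replicates,
both rank tests reject at 0.05 within +/-0.01.

# The phantom and what passing tests do (and do not) show

The generator reproduces the features the analysis depends on: walls of
known thickness (10 mm default; shell radii 20/30 mm) at 1.2 mm
isotropic resolution, scar patches filling the wall from the endocardial
side to a prescribed transmural fraction, HT rims (2.5 mm default)
around scar, infarct-like wall thinning (3 mm over a 10-degree taper —
this taper is where steep thickness gradients live), intensity classes
with additive Gaussian noise, mapping points exported in a rigidly
displaced frame with isotropic positional noise (0.2 mm default), and
kinematic two-wavefront activation maps. Diastolic points are seeded on
the scar border zone and thinned wall, normal points in remote healthy
wall — mirroring where diastolic and normal electrograms are found.

It does **not** emulate: MRI reconstruction artifacts, partial-volume
or bias fields, anisotropic voxels, fibre-orientation effects on
conduction or thickness, catheter contact/annotation error beyond
isotropic jitter, or electrogram morphology (activation times are
given, not detected). Consequently the end-to-end test demonstrates
that the *pipeline* preserves and detects the constructed contrasts —
thinner diastolic tissue, proximity to HT, proximity to steep thickness
gradients, non-transmural scar — not that the biological effect sizes
would be recovered from clinical images.

Default problem sizes (a 59-cube shell volume with ~4.6e4 wall voxels,
~1.5e4 mesh vertices, 100 points per category, 10,000 statistical
replicates) were chosen so the whole validation battery runs in a few
minutes on a single core while keeping every quantity's estimation
error well inside the tolerances being asserted.

# Degenerate inputs and tie-breaks (summary)

* All intensities equal: everything is scar (SI equals 100% of max);
  no error.
* Voxel adjacent to blood and background: endocardial (tie-break).
* Streamline stagnation or non-exit: node flagged undefined; a warning
  is raised when more than 5% of nodes are undefined.
* Wall components without any Dirichlet face: potential left NA with a
  warning (singular otherwise).
* Empty distance targets: infinite distances plus a warning.
* Nearest-node ties: lowest node id.
* Fewer than 3 non-collinear fiducials, mismatched counts, reflections:
  errors.

# Known limitations

* Pointwise potential accuracy is limited to ~0.03 at grid-tangent
  surface caps (above); thickness and transmurality are insensitive to
  this.
* The block-line centreline assumes chains are roughly monotone along
  their principal axis; strongly curved or branching block lines would
  be split or shortened.
* Distances are Euclidean, not geodesic; for strongly folded surfaces
  the two differ.
* The steep-gradient threshold is a package convention (0.5 mm/mm);
  absolute distance-to-steep-gradient values depend on it.
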