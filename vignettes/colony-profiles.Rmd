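---
title: "Normalized colony fluorescence profiles: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized colony fluorescence profiles: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Bacterial colonies grown for a few days on solid media are, to a good
approximation, geometrically similar: circularly symmetric domes whose
radius and height vary between replicates but whose shape does not.
`colonyprof` exploits that similarity. Every colony is mapped by a
similarity transformation — uniform scaling, rotation and translation,
the subgroup of affine maps that preserves angles and length ratios — onto
a dimensionless reference frame (`X, Y` in `[-1, 1]`, `Z` in `[0, 1]`).
In that frame a grid point means the same anatomical location in every
colony, so fluorescence can be averaged across replicates point by point
and dispersion quantified by the coefficient of variation (CV).

The pipeline is: sum projection of the detection channel; global
thresholding and binarization; connected-component labeling; moment-based
shape filters; extraction of the XY projection and the diametric XZ
cross-section per colony; principal-axis alignment of the XZ silhouette;
scale estimation (radius `R`, height `H`, base `h`); normalization;
scattered-data cubic interpolation onto fixed grids; replicate statistics;
and optional intensity normalization. The assumptions are explicit:
colonies are quasi-circular in top view (non-circular objects are
deliberately rejected, not rectified), their axial extent is bounded, and
the two fluorescence channels are acquired simultaneously so they share
geometry.

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold_factor` | 1.10 | — | multiplier on the mean projected intensity; the background/foreground split assumes colonies occupy a minority of the frame, which keeps the mean close to the background level |
| `min_equiv_circle_diameter_px` | 20 | px | minimum colony size, read as the area of a circle of that diameter (≈ 314 px²); `min_area_mode` also offers the literal-area and radius readings because the size rule is stated as an "equivalent circular area of 20 pixels", which admits all three |
| `max_axis_ratio_excess` | 0.15 | — | circularity tolerance: objects with `major/minor > 1.15` (merged colonies, smears) are rejected |
| `connectivity` | 8 | — | pixel adjacency for labeling; 8 matches common blob-detection practice, 4 is available |
| `xz_slab_rows` | 1 | rows | rows averaged around the centroid row for the XZ slice; >1 trades axial specificity for noise suppression |
| `grid_xy`, `grid_xz` | 256×256, 256×10 | points | reference-grid resolutions; chosen below typical image resolution so that grid cells contain data |
| `normalization` | raw | — | `raw` for fold-change comparisons under fixed microscope settings; `controls` anchors intensities to positive/negative control conditions; `minmax` rescales each profile to `[0, 1]` when settings cannot be standardized |
| `min_replicates_flag` | 10 | colonies | grid points supported by fewer replicates are flagged low-n: dispersion estimates degrade quickly below roughly ten replicates |

The minimum-area default deserves a note: a literal 20-pixel floor rejects
almost nothing at usual image sizes where colonies span thousands of
pixels, so the diameter reading is the default and the others remain
selectable.

# Geometry and units

Pixel indices are 1-based throughout (the natural R convention) and a
pixel's coordinate is its index, i.e. pixel centres; physical coordinates
are `(index - 1) × pitch`. All downstream geometry is centroid-centred, so
the index origin cancels.

XZ coordinates are converted to micrometres *before* alignment. Confocal
voxels are strongly anisotropic (e.g. 1.51 µm in XY vs several µm between
planes), and rotating raw index coordinates would not be an isometry; only
in physical units is the principal-axis rotation geometrically meaningful.
The rotation centre is the silhouette's mass centre (a rotation about any
other point differs only by a translation, which normalization removes).
The orientation estimate is the standard image-moments form
`theta = atan2(2 mu11, mu20 - mu02)/2` on the unweighted silhouette; the
cloud is rotated by `-theta`, which zeroes `mu11` analytically, so the
aligned silhouette is horizontal to machine precision.

In the normalized XZ frame the x-coordinate is divided by `R` expressed in
micrometres (`R × pixel_xy_um`); `R` itself is estimated in the XY plane in
pixel units. The z-coordinate is `(z - h)/H`.

The XZ silhouette is masked by comparing slice voxels against the same
frame threshold used for detection. That rule has a validity envelope: the
threshold scales like `1.1 × (background × N_planes + level × thickness ×
coverage)` (a projection-scale quantity) while a voxel carries `level`
alone, so the mask works when colony coverage times mean thickness (in
planes) stays below roughly 0.8. Typical sparse plates sit comfortably
inside this envelope; densely covered frames or very finely sampled stacks
can exceed it, in which case fewer or no silhouette voxels survive and the
colony is reported as degenerate in the audit table rather than silently
mis-measured.

# Interpolation

Values are interpolated with a reduced Clough–Tocher (Hsieh–Clough–Tocher)
element: each Delaunay triangle is split at its centroid into three cubic
Bézier patches, corner values and gradients fix the boundary ordinates, the
cross-edge normal derivative is constrained to vary linearly along each
outer edge, and C1 continuity across the internal edges yields the
remaining ordinates in closed form. Vertex gradients are estimated by
distance-weighted least squares over the one-ring neighbourhood, which is
exact for linear fields; with exact gradients the element reproduces
quadratics. The evaluator walks the triangulation for point location and
returns a sentinel (`NA`) outside the data hull — corners of the `[-1,1]²`
square are necessarily dataless for a disk-shaped colony and are never
extrapolated. Exact duplicate coordinates (several voxels mapping to one
normalized point) are averaged before triangulation.

The triangulation itself depends on the origin of the points. Colony
clouds always come from a pixel lattice, and lattice point sets are
maximally cocircular — every unit cell's four corners lie on one circle —
which general incremental Delaunay codes handle poorly (we observed the
s-hull implementation in the `interp` package returning triangulations
that failed to cover half the input sites on a rasterized disk). The
package therefore triangulates lattice-derived clouds directly from pixel
adjacency: two triangles per complete unit cell, a valid Delaunay
triangulation of the lattice (cocircular ties resolved by a fixed diagonal)
that the similarity transform carries along unchanged. Genuinely scattered
input falls back to `interp::tri.mesh`. The covered region is the union of
complete lattice cells — a subset of the convex hull, excluding only
boundary slivers that contain no interior data.

# Statistics and normalization

Per grid point, over the replicates valid there: mean, median, sample
standard deviation (n − 1 denominator; the estimator choice is ours, made
explicit here) and `cv = sd/mean`, with `NA` where the mean is zero or
fewer than two replicates overlap. Control-based normalization
`(M − C⁻)/(C⁺ − C⁻)` is applied to the per-condition replicate-mean
profiles; grid points where the controls coincide are invalid. Min–max
normalization is likewise applied to the aggregated mean profile per
condition and channel by default — normalizing each colony before stacking
answers a subtly different question (within-colony contrast rather than
between-condition placement) and is available behind the
`minmax_per_colony` flag.

CV heatmaps inherit a known edge effect: near the colony boundary, where
replicate hulls disagree and the interpolant is least constrained, both
the replicate count drops and the dispersion rises. The low-n flag exists
to keep such points visible but marked.

# The synthetic-colony generator

The generator is first-class, tested code, and defines the study
conditions used throughout the test suite. It emulates: dome-shaped
colonies (spherical cap by default, giving an analytic silhouette
`s(r) ≈ h(1 − r̂²)`; a truncated-Gaussian dome is available), circular XY
symmetry, colony-to-colony size variability (radii drawn from 30–52 px,
heights 10–18 µm in the default condition, i.e. up to ~1.7× spread),
baseline tilt implemented as a true rotation of the dome about its base
centre, programmable reporter patterns evaluated in each colony's own
normalized frame (uniform, central Gaussian, ring at normalized radius
`r0`), a constitutive detection channel at occupancy level 200 (a bright
boundary marker near the top of the 8-bit-like range — chosen so slice
voxels clear the projection-scale threshold discussed above), constant
background, and additive Gaussian noise clipped at zero. Intensities are
rounded to integer camera counts, which also makes stacks round-trip
bit-exactly through the TIFF writer and makes generation bit-reproducible
per seed.

What it does **not** emulate: the microscope point-spread function and
axial blur, depth-dependent attenuation, shot-noise statistics,
autofluorescence structure, non-circular or fractal colony morphologies,
and any growth biology. Passing tests therefore demonstrate that the
*computational* pipeline is correct and similarity-invariant on idealized
dome colonies — not that any particular biological claim holds on real
stacks.

Two quantitative consequences of the dome geometry are worth recording.
First, the XY projection of a volumetric reporter is the pattern times the
optical path length, `pattern(r̂) × s(r̂)`; for a Gaussian ring of width
`w` at radius `r0` the projected peak shifts inward by approximately
`w² · 2r0/(1 − r0²)` (≈ 0.03 for the default `w = 0.12`, `r0 = 0.6`).
Ring-recovery checks use a 0.05 window around `r0`, which accommodates
this bias on top of radial binning. Second, the projection is quantized by
the finite number of Z planes; profile values step wherever the dome
surface crosses a plane boundary.

# Discretization tolerances

The similarity-invariance check compares a colony against its ×2-scaled
twin after min–max normalization (projected intensity scales with path
length, an intensity effect the method's own normalization removes). The
documented tolerance is **0.15 maximum absolute difference** on the
`[0, 1]` scale, budgeted as: interpolation error `~h²·|f″|` at the coarser
colony's pixel pitch (h ≈ 1/30 of the radius against the ring curvature
`1/w²` gives ≈ 0.05), plus the Z-plane quantization of the projection
(≈ one plane in ~10 at the ring for the 0.75 µm fixtures), plus cubic
overshoot near those steps. Measured values sit near 0.05 (XY) and below
0.01 (XZ). Alignment recovery is tested to 1e−3 rad on densely sampled
silhouettes (the estimate is exact for an exactly rotated cloud; the
tolerance absorbs voxelization of generated tilted colonies, tested with
sub-micrometre Z sampling). Linear-field reproduction on the default
grids is tested to 1e−6, and interpolation at a data site to 1e−9.

# Degenerate inputs and tie-breaks

Flat colonies (single plane, zero height) and colonies whose silhouette is
empty at the frame threshold raise classed degenerate-colony errors and are
recorded in the audit table with the rule that fired; collinear XZ clouds
raise alignment errors; fewer than four or collinear points raise
interpolation errors, skipping the colony and continuing the run. A
constant profile makes min–max normalization undefined (error), and
coincident controls make control normalization undefined (all-invalid with
a warning). Ties in the mini-patch choice at Clough–Tocher split boundaries
are benign: the patches agree along shared edges by construction.

# Problem sizes

The test-suite and acceptance runs use frames of 128–640 px square with
8–40 planes, colonies of 22–60 px radius, 12-colony conditions, and grids
from 32×32 up to the full 256×256/256×10 defaults — sizes chosen so the
whole suite exercises every code path, including the default grids, while
a complete run stays in the minutes range on a single core. Real 1024×1024
stacks process at a few seconds per colony, dominated by the
256×256-point interpolation.

# Known limitations

Non-circular geometries are out of scope by design: the axis-ratio filter
rejects them rather than attempting modal matching or other
general-shape registration. The XZ cross-section is a single diametric
plane (optionally a thin slab) — a full 3D reconstruction is not
attempted. The silhouette threshold inherits the validity envelope above.
Reading native microscope-vendor formats is not supported; convert to
OME-TIFF (the reader honours embedded OME-XML pixel sizes and channel
layout) or plain multi-page TIFF with a declared layout.
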