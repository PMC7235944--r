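---
title: "Methods: trabecular bone morphometry in trabemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trabecular bone morphometry in trabemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabemorph)
```

## Why this package exists

Micro-CT morphometry of trabecular bone reduces a segmented 3D image to a
handful of scalars: bone volume fraction (BV/TV), bone surface (BS),
trabecular thickness and separation (Tb.Th, Tb.Sp), and the degree of
anisotropy (DA). Although the parameters have textbook definitions, analysis
tools disagree on the same image — sometimes by a few percent (BS with or
without artificial cut surfaces), sometimes dramatically (DA, where both the
mean-intercept-length acquisition and the eigenvalue normalisation vary
between implementations). `trabemorph` implements each parameter with its
implementation variants exposed as explicit, labelled switches, so the
sources of disagreement can be isolated and quantified on phantoms with
analytic ground truth.

All computations assume a binary (0/1) volume with isotropic voxels of side
`h` millimetres, indexed `[z, y, x]`. The total volume TV is always the full
cubical region of interest (ROI); the ROI faces are artificial cut planes,
not biological surfaces, and every variant switch in the package is about
how those planes are treated.

## Segmentation chain

`segment()` reproduces a standard micro-CT preprocessing pipeline:

1. Gaussian filter, `sigma = 1.2` voxels, kernel truncated at
   `support = 2` multiples of sigma (radius `ceiling(2 * 1.2) = 3` voxels),
   separable convolution with symmetric (mirror) boundary handling;
2. single-level threshold (values strictly above become bone);
3. removal of unconnected foreground (largest 26-connected component kept;
   ties broken toward the component with the earliest `(z, y, x)` voxel);
4. morphological closing, then opening, with a cubic structuring element
   (default 3 voxels per side).

Two conventions here are genuinely open and we chose once:

* **"support = 2" as kernel truncation.** We read the filter support as the
  truncation radius in multiples of sigma, the common vendor convention.
  Both sigma and support are configurable.
* **The "3 x 3" kernel acts in 3D.** Inputs are volumes, so the default
  structuring element is a 3x3x3 cube; `morph_3d = FALSE` switches to
  per-slice 2D squares for sensitivity checks.
* **Morphology never erodes the cut planes.** Erosion pads the outside with
  foreground and dilation with background, so closing/opening are identities
  on structures cut flat by an ROI face. With the naive
  outside-as-background convention, closing removes one voxel from every
  face-touching structure at every pass — an artifact, not morphology.

Re-segmenting a binary mask at threshold 0.5 is exactly idempotent for flat
interfaces (the Gaussian is symmetric, so the mid-level crossing does not
move). Curved interfaces shrink by approximately `sigma^2 * curvature`
voxels per pass and convex corners erode; the idempotence property is
therefore tested on plate phantoms, and should not be expected bit-exactly
on curved anatomy.

## Phantoms and what they stand for

`make_phantom()` generates binary volumes with analytic ground truth, the
test surface standing in for real bone:

| kind | ground truth | probes |
|---|---|---|
| `plate_stack` (t fg / g bg layers) | Tb.Th = t·h, Tb.Sp = g·h, BV/TV = t/(t+g) | thickness, MIL ordering |
| `rod_array` (diameter d, spacing s) | Tb.Th = d·h, strong DA along axis | thickness, DA direction |
| `sphere` (radius r) | BS = 4πr²h², volume = 4/3·πr³h³ | surface, enclosed volume |
| `solid_cube` | BV/TV = 1, interior BS = 0 | degenerate handling |
| `isotropic_foam` | target BV/TV, DA ≈ 1 | realistic topology, isotropy |

The foam is a Gaussian random field: seeded white noise smoothed at the
stated correlation length (default 3 voxels) and thresholded at the quantile
matching the target volume fraction (default 0.25, a typical trabecular
value). It is rotation-invariant in distribution and has exact
volume-fraction control. Default extent is 128³ voxels at h = 0.018 mm —
micro-CT resolution at desk scale; the tests use 24³–132³ volumes chosen so
each check runs in seconds while keeping at least a dozen structural
features per axis (plate dims are whole multiples of the period t+g so the
realized volume fraction equals the analytic one).

What the phantoms do **not** emulate: scanner noise and beam hardening,
partial-volume gray levels, plate-rod mixtures, curved and perforated
trabeculae, or anatomical gradients. Passing the oracle suite shows the
algorithms implement their definitions correctly at this resolution; it does
not certify accuracy on real anatomy, where segmentation quality and
resolution dominate.

Rods are discretised by the center-distance test (voxel center within d/2 of
the rod axis), which carries up to one voxel of error on the diameter.

## Surface extraction and the boundary variant

`triangulate()` extracts the bone/marrow interface at iso-level 0.5 between
voxel centers by marching tetrahedra on the uniform 6-tetrahedron (Kuhn)
subdivision of each inter-center cell. On binary data every crossing vertex
is an edge midpoint, and because the subdivision is face-consistent across
cells the mesh is watertight by construction. We chose marching tetrahedra
over the classic marching-cubes case table deliberately: the classic table
has ambiguous face configurations that can open cracks on random binary
structures, and downstream operations here (enclosed volume, the surface
partition identity) require closed meshes unconditionally. The cost is more
triangles (up to 2 per tetrahedron) and slightly different chamfering at
edges; flat axis-aligned interfaces are reproduced exactly, and a 20³-voxel
cube's area is recovered within 1.5%.

With `cap_boundary = TRUE` the volume is conceptually padded by one
background layer, closing foreground at the ROI faces with cap triangles on
the cut planes (half a voxel outside the outermost voxel centers). A
triangle is flagged `is_boundary` when **all three of its vertices lie on
cut planes** — not necessarily the same plane, so the chamfer strips along
ROI edges and corners count as artificial too; a whole-ROI solid then has
zero non-boundary area, as it should. `bone_surface(include_boundary =
FALSE)` subtracts exactly the flagged area: the include/exclude variants
differ by the summed boundary-triangle area as an identity, which is the
mechanism behind the large inter-tool BS differences.

BV from the mesh (`bvtv_mesh`) is the signed-tetrahedron volume enclosed by
the capped mesh divided by TV. It differs from voxel counting only by
sub-voxel surface placement; on smooth phantoms the two agree within 0.003
absolute. An uncapped mesh has no defined interior and is rejected.

## Local thickness

`local_thickness()` implements maximal-inscribed-sphere thickness: every
phase voxel is assigned the diameter of the largest sphere fully inside the
phase that covers it. Tb.Sp is by definition the same computation on the
background; the package computes it literally as thickness of the
complemented image, so the identity `tb_sp(img) == tb_th(!img)` is exact.

The pipeline is: exact Euclidean distance transform (separable
lower-envelope algorithm, not a chamfer approximation — chamfer metrics bias
thickness by several percent, which matters when inter-tool gaps of that
size are the object of study); distance-ridge pruning (spheres contained in
a neighbour's sphere are redundant and never painted); and sphere-coverage
propagation from the largest radius down.

The discrete calibration: for a voxel at center-to-nearest-background
distance `r` (voxel units), the assigned diameter is `(2r - 1) * h`, and the
sphere at `c` covers voxels with `|x - c| <= r` (an exact integer
comparison on squared distances). This makes a single voxel report one
voxel diameter and an n-layer slab report exactly `n * h` for odd n. Even
widths are quantised one voxel low — the odd-diameter sphere family cannot
represent them — and voxelised cylinders read about 0.8 voxels low; both sit
within the one-voxel tolerance the oracle suite asserts.

Edge policies at the ROI faces:

* `include_edges` (default): the cut planes act as phase boundary; spheres
  may not leave the ROI. Every voxel enters the statistics, but structures
  running into a face are under-measured nearby — visible as a rim of low
  values in exported thickness maps, and the reason wide plate gaps read
  more than a voxel low under this policy at 128³.
* `exclude_edge_voxels`: spheres may overhang the faces (the structure is
  treated as continuing), and voxels whose maximal sphere is truncated by a
  face are flagged and omitted from `tb_stats()`. This removes the edge bias
  at the cost of a smaller sample; it mimics tools that skip the edge
  region, and it is the policy under which the plate/rod oracle suite is
  evaluated.

For structures fully interior to the ROI the two policies agree exactly.
Thickness is equivariant under axis permutations and monotone under
foreground dilation (both tested).

## Mean intercept length and the fabric tensor

Two acquisition methods, as found across tools:

* **Parallel test lines** (`mil_test_lines`): directions are deterministic
  Fibonacci-spiral points on the hemisphere; for each direction a parallel
  line grid (spacing 1 voxel by default, seeded random in-plane offsets) is
  clipped to the ROI and sampled at 0.5-voxel steps;
  background-to-foreground transitions are counted. MIL(n) = total clipped
  line length / crossing count. Directions with zero crossings are excluded
  from fitting rather than imputed (imputation would bias the tensor for
  sparse structures).
* **Projected triangulated surface** (`mil_surface_projection`):
  MIL(n) = 2·BV / P(n) with P(n) the non-boundary surface area projected
  along n (`sum(|t_normal . n| * area) / 2`); boundary triangles are
  excluded since cut planes carry no structural orientation.

The two definitions deliberately differ in scale: the test-line convention
above measures mean spacing between interfaces along the whole line, while
2·BV/P is the mean bone chord; they differ by the constant factor
2·BV/TV, which is direction-independent and cancels in DA. Only direction
agreement between methods is asserted, mirroring the fact that tools using
different acquisitions agree on orientation but not on DA magnitude. Note
also that on voxelised data the projected-area method inherits staircase
anisotropy: the projection of an axis-aligned faceted surface is genuinely
direction-dependent (up to tens of percent on a voxelised ball even after
chamfering), so its isotropy is verified against an analytic smooth sphere
mesh, not a voxelised one.

`fit_mil_ellipsoid()` fits the quadratic form `n' A n = 1 / MIL(n)²` by
least squares over the six independent components of the symmetric tensor A
(the fitted quantity is recorded in the result; fitting MIL itself instead
of 1/MIL² would change the ellipsoid). At least six usable directions
spanning 3D are required; a non-positive-definite fit is an error rather
than a silently clamped result. One genuinely degenerate case is worth
knowing: ideal full-extent plate stacks have diverging in-plane MIL, so two
eigenvalues tend to zero and the fit correctly refuses — real (finite,
perforated) plates do not do this.

DA conventions, all from the same eigenvalues and all recorded in the
result: `eigen_ratio` = λmax/λmin (the package default), `semi_axis_ratio`
= its square root (the MIL ellipsoid axis ratio), and `one_minus_inverse` =
1 − λmin/λmax in [0, 1). Tools differ in exactly this normalisation, which
alone produces large apparent DA disagreements; converting between
conventions is closed-form, so the package computes one fit and derives all
three.

Defaults: 128 directions, line spacing 1 voxel, offset seed 0. On the
isotropic foam at 64³ the test-line DA lands between 1.05 and 1.2 across
seeds; increasing the direction count shrinks its variance (tested).

## Agreement analysis

`compare_variants()` reproduces the comparison-study workflow over a
long-format results table: per-sample percent differences (normalisation
selectable: reference = second label, reference = first, or pair mean —
reported, since published tables rarely state it), mean ± SD with the SD on
n−1, Bland–Altman limits at mean ± 1.96·SD, and the regression of the first
label on the reference with R² = squared Pearson correlation (a variant
running 5% high has slope 1.05 with the reference on the x-axis).
`plot_agreement()` draws the standard two panels: regression with identity
line, and Bland–Altman with solid mean and dashed limits.

## Numerical and degenerate-input choices

* Binary masks are 8-bit 0/255 on disk; on reading, values above half the
  on-disk maximum map to 1 (guards against lossy intermediates). In-memory
  axis order is fixed `[z, y, x]` across TIFF, MetaImage and NIfTI; MHD raw
  data is written x-fastest.
* Anisotropic voxel spacing in file metadata is an error (the morphometry
  assumes isotropy), overridable by an explicit `voxel_size`.
* Empty phases raise errors naming the phase; a solid or empty volume has
  no MIL; empty meshes are valid with zero area. Pipelines therefore cannot
  silently mix conventions. `analyze_volume()` converts these errors to
  `NA` per parameter so batch runs complete, and `run_analyze()` logs and
  skips failing samples.
* `crop_roi` uses zero-based corners, matching exported metadata indices.
* All stochastic stages (foam noise, line-grid offsets) are seeded; a rerun
  from the same configuration is bit-identical, which `run_analyze()`
  exploits to make its results CSV reproducible byte for byte.

## Known limitations

* Thickness of even-width structures is one voxel low by construction
  (odd-diameter sphere family); halving the voxel size halves the bound.
* The `include_edges` thickness policy under-measures structures that run
  into the ROI faces; use the exclude policy (or larger ROIs) when the edge
  region matters.
* Projected-surface MIL on voxelised data carries staircase anisotropy;
  the test-line method is the robust default for DA on binary volumes.
* No greyscale sub-voxel interpolation anywhere: the package operates on
  the segmented mask, so its numbers reflect the mask, not the scan.
* Proprietary scanner formats (ISQ/AIM, DICOM) and adaptive thresholding
  are out of scope.
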