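---
title: "Methods: CT/SLI puncture navigation in punctnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT/SLI puncture navigation in punctnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

punctnav implements the computational chain of a CT + structured-light
(SLI) guided orthopedic puncture navigation system: build a preoperative
navigation map from CT, register the intraoperative surface scan to it,
track the puncture guiding tube, and quantify the drift and mismatch that
accumulate between the virtual and the real scene. This vignette documents
the models, the parameters that matter, the numerical choices, and what the
synthetic phantom does and does not establish about real data.

## Coordinate conventions

All coordinates are millimetres, right-handed. Volumes use a voxel-center
convention: world position = `origin + (index − 1) · spacing`, with the
origin at the center of the first voxel. Rigid transforms act as
`p → R p + T`; `compose_transforms(first, second)` is "apply `first`, then
`second`". The registration's CT→SLI mapping is `M_SLI = R·M_CT + T` and
factors as `R = R_FM · R_ICP`, i.e. the ICP correction acts in CT space
*before* the coarse feature-match transform. This order is not arbitrary:
the ICP aligns the (partial) scan cloud onto the CT model, and inverting
that incremental solution to CT→SLI lands exactly on that factorization.
The additive translation shortcut `T = T_FM + T_ICP` is exact only when the
fine rotation is the identity; `compose_transforms(..., translation =
"additive")` reproduces it for comparison, but the exact composition
`T = R_FM·T_ICP + T_FM` is always the default.

## Navigation map from CT

Segmentation is plain Hounsfield thresholding with the clinical presets
(body surface −650 HU→max, which keeps soft tissue and bone and drops air
at −1000 HU; skeleton 125 HU→max). The interactive mask-editing /
region-growing steps of a navigation workstation are replaced by a
deterministic largest-connected-component selection (26-connectivity by
default) plus optional morphological closing — an automation choice, made
so the map is reproducible from the volume alone. No smoothing is applied
to reconstructed models.

Isosurfaces are extracted at the 0.5 level of the binary mask with a
surface-net (dual-contouring) algorithm: one vertex per mixed-occupancy
dual cell, placed at the mean of the cell's edge-crossing midpoints, one
quad per sign-change voxel edge. On binary data this has the same
edge-midpoint geometry as marching cubes, is watertight by construction
(the mask is padded with an empty border), and needs no case tables. On a
voxelized 20 mm ball at 1 mm spacing the mesh area is within 2.5% of the
analytic sphere and the enclosed volume within 1%; vertices always lie
within one voxel diagonal of the true boundary. The segmentation thresholds
are deliberately the single source of truth: we contour the binarized mask,
not the HU field.

## Two-step registration

**Coarse.** Landmarks are explicit correspondences on conspicuous surface
features (on phantoms, the bandage-ridge apexes). The closed-form Kabsch
solution (centroid alignment, SVD of the cross-covariance, determinant
correction to keep the rotation proper) minimizes the landmark
least-squares error. Three non-collinear pairs are the mathematical
minimum; collinear configurations are rejected via the second singular
value.

**Fine.** Trimmed ICP moves the scan cloud onto the CT mesh. Per run, a
subsample (default 5,000 points) is drawn **once**; each iteration finds
exact nearest points on the mesh (KD-tree-bounded exact
closest-point-on-triangle queries — at drift scales of a few hundredths of
a millimetre, approximate neighbours are not acceptable), discards the
`trim_fraction` (default 0.2) largest-distance pairs plus anything beyond
`max_pair_distance`, and applies a rigid update. Drawing the subsample once
rather than per iteration keeps the trimmed objective fixed, which is what
makes the error trace interpretable (and monotone for the point-to-point
update, the classical trimmed-ICP argument); restarts redraw it.

Two update rules are provided. `point_to_point` is the textbook SVD update
with a monotone non-increasing RMS trace. It converges, however, only
tangentially-slowly on one-sided scans of smooth surfaces: from a 1° initial
offset it still sits at ~0.02 mm RMS after 300 iterations, because
closest-point correspondences do not penalize sliding along the surface.
`point_to_plane` (the default against mesh targets) performs a Gauss–Newton
step on the normal-projected residual and reaches machine precision in
under ten iterations on the same data. This is the package's reading of an
"improved speed-up" ICP; the classical variant remains available and is
what the monotonicity property is asserted on.

**Gate.** After ICP, the distance test is recomputed on the *full* cropped
cloud against the transformed model (the strictest reading of a single
reported RMS per specimen), point-to-surface by default. If the RMS exceeds
`quality_threshold` (default 1.0 mm — the acceptance threshold is a package
default, not an empirically reported value, and is exposed in the config),
ICP restarts with a new subsample seed up to `max_restarts` (default 3)
times and the best result is returned with a `converged` flag.

Scan preprocessing (`crop_and_denoise`) is an axis-aligned crop plus
statistical outlier removal: keep points whose mean distance to their
`nn_k = 8` nearest neighbours is within `mean + 2·SD` of that statistic's
distribution.

## Guiding-tube tracking

The SLI camera sees roughly half the tube circumference, so the cylinder
fit must work on partial angular coverage; below ~120° of coverage fits
become unstable (documented limitation). The RANSAC minimal sample is two
points with normals: the candidate axis is `n₁ × n₂` (the normal of a
cylinder is everywhere perpendicular to its axis), the axis point comes
from intersecting the two inward normal lines in the axis-orthogonal plane,
and the radius from the sample's axis distances. Near-parallel normal pairs
are skipped. Consensus counts points with `|distance to axis − radius| ≤
distance_threshold` (default 0.6 mm).

The best candidate is refined by Gauss–Newton with an analytic Jacobian
over four parameters (two axis tilts, two in-plane axis-point offsets; the
radius is profiled out as the mean axis distance). A second pass re-selects
points on a robust band (2.5 × MAD of the residuals, capped by the RANSAC
threshold) before the final refinement: without it, stray points that
happen to fall inside the consensus shell bias the radius by ~0.2 mm when
surface noise is comparable to the band width. Finite-difference optimizers
were rejected here: their gradient error floors the solution near 1e−6,
which breaks exact rigid-equivariance of the fit; the analytic Gauss–Newton
converges to machine precision. The tube length is the extent of the
largest axially *contiguous* run of inlier projections (gap threshold
`max(1 mm, 20 × median gap)`) — in-shell outliers beyond the physical tube
ends would otherwise inflate it by millimetres. The returned inlier flags
are the plain radial band re-scored against the returned model, so
re-scoring reproduces them exactly.

Deviation from the planned path reports the orientation-agnostic
axis-to-direction angle, the lateral offset of the planned entry from the
infinite tube axis, and the tip gap from the nearer tube end to the entry.
The intraoperative pass/fail gate defaults to 3° and 2 mm (package
defaults, exposed in the config; boundaries inclusive).

## Drift and cohort statistics

Surface and skeletal drift use the distance test function: exact per-vertex
nearest-surface distances after applying the relevant alignment, summarized
as RMS / mean / SD / max, and exportable as a PLY heat map (distances in
the `quality` property, 8-bit blue→green→red ramp clamped to 0–1 mm by
default). Skeletal drift is measured *residual to the surface
registration*: the preoperative bone rides along with the pre/post surface
alignment and the remaining distance to the postoperative bone is the drift
the surface cannot explain.

A caveat worth stating: nearest-surface distances under-report any
displacement component tangential to the surface (points slide along the
closest geometry). For recovery of a *known* injected displacement between
meshes of identical connectivity, the `point_to_point` metric
(corresponding-vertex displacement) is therefore used; the point-to-surface
metric remains the default for real, independently segmented surfaces where
no correspondence exists.

Cohort results are reported as M ± SD with the **sample** (n−1) standard
deviation — the convention that reproduces the shipped specimen table's own
bold row (the population convention does not). Display rounding is three
decimals, half-away-from-zero; raw values are never rounded internally.
Paired comparisons report the paired t statistic with n−1 degrees of
freedom and a two-sided p value (auxiliary outputs, not gates). The shipped
20-specimen table has one internal inconsistency: its surface-drift rows
recompute to SD ≈ 0.027 mm while the table's summary row prints 0.272 (and
the accompanying text a third value); the package reports the recomputed
statistic and treats the per-specimen rows as ground truth. Recomputed
means can also differ from printed summary rows by one unit in the third
decimal, because the rows themselves are printed rounded.

## The phantom: what it emulates, and what it does not

The synthetic specimen is a tapered elliptical cylinder (defaults: 160 mm
long, 45 × 40 mm proximal semi-axes, taper 0.85) carrying six Gaussian
ridges (4 mm apex height) that play the role of hardened-bandage fixture
features — their apexes are the coarse-registration landmarks — plus an
offset bone (14 mm mean radius, 1 mm cortical bumps) kept at >2 mm
clearance inside the skin. Voxelization assigns −1000 HU (air), 40 HU
(soft tissue), 700 HU (bone), so the clinical threshold presets recover
the structures exactly by construction.

The scan simulator is a pinhole stand-in for the SLI module: one ray per
image cell, first intersection only (hidden surfaces absent, as in a real
one-sided scan), Gaussian depth noise along the ray (default σ = 0.1 mm,
consistent with sub-millimetre system-level registration), and random
dropout. Default geometry: camera 1.2 m from the scene with a ~30°
horizontal field of view and a 320 × 240 ray grid. Structured-light
*decoding* (fringe projection, phase unwrapping) is deliberately not
simulated — the generator produces the decoder's output. All generators are
reproducible bit-for-bit given (spec, seed).

What passing phantom tests does **not** show about real data: no CT
artifacts (beam hardening, motion, partial volume), no soft-tissue
deformation (the phantom is rigid, as a surface-fixed specimen is intended
to be, but real tissue is not), no specular or interreflection artifacts in
the scan, Gaussian-only depth noise, and landmark correspondences given
exactly rather than picked by an operator. The cohort statistics, by
contrast, are computed from the shipped per-specimen table and involve no
simulation.

## Problem sizes and numerical choices

Test and acceptance runs use: 1 mm voxel spacing (≈100 × 90 × 170 voxel
volumes, ≈125k-face surface meshes), scan grids of 320 × 240 rays
(≈2,500–3,500 surface points on the phantom), ICP subsamples of
1,200–2,000 points with at most 40–60 iterations, 20 registration seeds at
σ = 0.3 mm, 20 cylinder seeds on 2,000-point tube clouds with 25% outliers,
and 10 end-to-end drift seeds — sizes chosen so the full suite completes in
a couple of minutes while the Monte-Carlo medians are stable. ICP declares
convergence at a relative trimmed-RMS change below 1e−6 or an absolute RMS
below 1e−9 mm (numerically exact alignment). Degenerate inputs error
explicitly rather than silently: empty masks, uniform masks, collinear
landmarks, all-gated correspondence sets, sub-minimal consensus.

## Known limitations

- Rigid transforms only; no deformable registration or scale recovery.
- No global (landmark-free) initial alignment; coarse features are inputs.
- Surface-net meshes shrink convex features slightly (~2% area on a 20 mm
  sphere at 1 mm spacing); at clinical drift scales this matters only
  through the registration's discretization floor (~0.05 mm pose error when
  registering analytic geometry against a 1 mm-voxel model).
- Cylinder fits need ≥120° angular coverage and benefit from
  grid-structured sampling for normal estimation; k = 12 PCA normals on
  sparse irregular clouds carry multi-degree tails.
- The t statistics assume independent specimens; no hierarchical structure
  is modelled.
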