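# punctnav

Software core of a CT + structured-light-imaging (SLI) guided orthopedic
puncture navigation workflow, for surgical-navigation researchers and
engineers who need a reproducible, scriptable reference implementation of
the geometry pipeline behind such systems.

Image-guided puncture navigation maps a preoperative plan (virtual space)
onto the intraoperative scene (real space). Any change in that mapping
during surgery — *image drift and mismatch* — directly degrades needle
placement. This package implements the computational chain that builds the
map, maintains it intraoperatively, tracks the instrument, and quantifies
the drift:

1. **CT navigation map** — Hounsfield-unit threshold segmentation (body
   surface −650 HU→max, skeleton 125 HU→max), largest-component cleanup,
   isosurface extraction to triangle meshes, and puncture-path planning.
2. **Two-step registration** — coarse landmark alignment (Kabsch:
   centroid + SVD with determinant correction) on conspicuous
   bandage-fixture features, refined by trimmed ICP of the one-sided SLI
   surface cloud against the CT mesh. The CT→SLI mapping is
   `M_SLI = R · M_CT + T` with `R = R_FM · R_ICP`; quality is gated by the
   RMS of the full cloud's exact nearest-surface distances.
3. **Guiding-tube tracking** — RANSAC cylinder fitting (two-point minimal
   sample with normals: candidate axis `n₁ × n₂`), Gauss–Newton refinement,
   and deviation scoring (angle, lateral offset, tip gap) against the
   planned path.
4. **Drift assessment** — exact point-to-surface distance fields, RMS /
   M ± SD summaries, paired t statistics, and per-vertex heat-map export;
   skeletal drift is measured residual to the surface registration.
5. **Phantom simulator** — a limb-like synthetic phantom (tapered
   elliptical skin with ridge landmarks, offset bumpy bone), CT
   voxelization, pinhole structured-light scan simulation with depth noise
   and dropout, partial tube clouds with outliers, and known-drift
   injection, so every stage has a generate-and-recover test.

Geometry kernels (KD-tree, exact point-to-triangle distance, surface-net
isosurfacing, ray casting, scanline voxelization) are implemented in C++
via Rcpp. File formats: STL, PLY (ascii/binary), XYZ, NIfTI, NRRD.

## Worked example

```r
library(punctnav)

# synthetic specimen and its CT
ph   <- make_phantom(phantom_spec(seed = 0))
vol  <- voxelize_ct(ph$skin, ph$bone, spacing = 1)
surf <- segment_model(vol, "surface")

# intraoperative scene: specimen posed in camera space, scanned with
# 0.1 mm depth noise
pose  <- rotation_transform("z", 8, c(25, -10, 5))
posed <- apply_transform(surf, pose)
ctr   <- colMeans(posed$vertices)
scan  <- simulate_sli(posed, sli_camera(position = ctr + c(0, -1200, 0),
                                        look_at = ctr, noise_sigma = 0.1))

# two-step registration from ridge landmarks + trimmed ICP
lm  <- list(src = ph$landmarks, dst = apply_transform(ph$landmarks, pose))
res <- register_two_step(scan, surf, lm, icp_params(seed = 0))
res
#> registration_result: rms 0.0816 mm, 11 ICP iterations, converged

# track the guiding tube against a planned path
path <- plan_path(ctr + c(0, -40, 20), ctr + c(5, 0, -15))
tube <- cylinder_model(path$entry + 40 * path$direction, path$direction, 5, 80)
fit  <- fit_cylinder_ransac(make_tube_cloud(tube, 180, 2000, 0.2, 0.1, seed = 1),
                            ransac_params(seed = 0))
path_deviation(fit$model, path)
#> path_deviation: angle 0.045 deg, lateral offset 0.050 mm, tip gap 0.068 mm
```

The registration RMS (~0.08 mm here, set by the 0.1 mm scan noise) is the
distance-test value that gates acceptance in the operating room; the
deviation block is the real-time feedback a surgeon would see before
advancing the needle (the tip gap is the distance from the tube end nearer
the skin entry to the planned entry point).

Cohort statistics of the shipped 20-specimen alignment/drift table:

```r
s <- summarize_drift_table()
format(s$columns$rms_ct_sli)      # "0.575 ± 0.146"  (CT vs intraoperative SLI)
format(s$columns$skeletal_drift)  # "0.235 ± 0.197"  (pre/post skeletal drift)
s$paired$skeletal_minus_surface$mean  # 0.20225 — bone drifts more than skin
```

A command-line wrapper is installed as `exec/punctnav` with subcommands
`simulate`, `segment`, `register`, `track-tube`, `drift`, `summarize`,
`pipeline` and `config`; `run_pipeline()` is the same end-to-end
orchestration as an R function.

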