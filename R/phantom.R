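## Synthetic limb phantom: stands in for the cadaver specimen and the
## structured-light hardware so every pipeline stage has a
## generate-and-recover test with known ground truth. The skin is a tapered
## elliptical cylinder carrying Gaussian ridge bumps that emulate the
## conspicuous features on hardened bandage fixtures (their apexes are the
## coarse-registration landmarks); the bone is an offset bumpy cylinder
## strictly inside the skin.

#' Phantom shape specification
#'
#' Dimensions are mm. Defaults describe a desk-scale lower-limb segment:
#' 160 mm long, elliptical cross-section 45 x 40 mm tapering to 85% at the
#' distal end, six 4 mm bandage ridges, and a 14 mm bone offset 6 mm from the
#' skin axis with 1 mm cortical bumps.
#'
#' @param length skin length along z.
#' @param radii length-2 vector: proximal ellipse semi-axes (x, y).
#' @param taper distal/proximal scale factor in (0, 1].
#' @param ridge_count number of ridge landmarks.
#' @param ridge_height ridge apex height above the base surface.
#' @param ridge_sigma ridge Gaussian footprint: length-2 (angular mm-equiv,
#'   axial mm).
#' @param bone_radius mean bone radius.
#' @param bone_offset length-2 vector: bone axis offset in x, y.
#' @param bone_bump bone surface bump amplitude.
#' @param seed integer; jitters ridge placement deterministically.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(length = 160, radii = c(45, 40), taper = 0.85,
                         ridge_count = 6L, ridge_height = 4, ridge_sigma = c(12, 8),
                         bone_radius = 14, bone_offset = c(6, 0), bone_bump = 1,
                         seed = 0L) {
  stopifnot(length > 0, all(radii > 0), taper > 0, taper <= 1,
            ridge_count >= 0, ridge_height >= 0, bone_radius > 0, bone_bump >= 0)
  structure(list(length = length, radii = radii, taper = taper,
                 ridge_count = as.integer(ridge_count), ridge_height = ridge_height,
                 ridge_sigma = ridge_sigma, bone_radius = bone_radius,
                 bone_offset = as.numeric(bone_offset), bone_bump = bone_bump,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## base semi-axes at height z
.phantom_axes <- function(spec, z) {
  s <- 1 - (1 - spec$taper) * z / spec$length
  cbind(spec$radii[1] * s, spec$radii[2] * s)
}

## ridge centers (theta, z), deterministically jittered by seed
.phantom_ridges <- function(spec) {
  m <- spec$ridge_count
  if (m == 0L) return(cbind(theta = numeric(0), z = numeric(0)))
  jit <- .with_seed(spec$seed, runif(2L * m, -1, 1))
  theta <- (seq_len(m) - 1) * 2 * pi / m + 0.08 * jit[seq_len(m)]
  zfrac <- 0.2 + 0.6 * ((seq_len(m) - 0.5) %% 3) / 3 + 0.03 * jit[m + seq_len(m)]
  cbind(theta = theta, z = spec$length * zfrac)
}

## total ridge height field h(theta, z)
.ridge_height_at <- function(spec, theta, z) {
  rid <- .phantom_ridges(spec)
  h <- numeric(length(theta))
  if (nrow(rid) == 0L) return(h)
  # angular distance converted to arc length at the mean radius
  rmean <- mean(spec$radii)
  for (i in seq_len(nrow(rid))) {
    dth <- atan2(sin(theta - rid[i, 1]), cos(theta - rid[i, 1]))
    h <- h + spec$ridge_height *
      exp(-0.5 * ((dth * rmean / spec$ridge_sigma[1])^2 +
                  ((z - rid[i, 2]) / spec$ridge_sigma[2])^2))
  }
  h
}

## bone radius at circular angle phi and height z
.bone_radius_at <- function(spec, phi, z) {
  spec$bone_radius + spec$bone_bump * sin(3 * phi + 2 * pi * z / spec$length)
}

.bone_z_range <- function(spec) c(0.08, 0.92) * spec$length

.parametric_tube <- function(xy_fun, z_lo, z_hi, n_theta, n_z) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(z_lo, z_hi, length.out = n_z)
  grid <- expand.grid(theta = th, z = zs)
  xy <- xy_fun(grid$theta, grid$z)
  V <- cbind(xy, grid$z)
  nv <- nrow(V)
  # side quads
  idx <- function(i, j) (j - 1L) * n_theta + i          # i: theta, j: z
  i <- rep(seq_len(n_theta), n_z - 1L)
  j <- rep(seq_len(n_z - 1L), each = n_theta)
  inext <- ifelse(i == n_theta, 1L, i + 1L)
  f1 <- cbind(idx(i, j), idx(inext, j), idx(inext, j + 1L))
  f2 <- cbind(idx(i, j), idx(inext, j + 1L), idx(i, j + 1L))
  # end caps: fan to centroids
  clo <- nv + 1L; chi <- nv + 2L
  V <- rbind(V, c(colMeans(V[seq_len(n_theta), 1:2, drop = FALSE]), z_lo),
             c(colMeans(V[idx(seq_len(n_theta), n_z), 1:2, drop = FALSE]), z_hi))
  i <- seq_len(n_theta); inext <- c(seq_len(n_theta)[-1], 1L)
  cap_lo <- cbind(clo, inext, i)
  cap_hi <- cbind(chi, idx(i, n_z), idx(inext, n_z))
  tri_mesh(V, rbind(f1, f2, cap_lo, cap_hi))
}

#' Generate the limb phantom meshes and landmarks
#'
#' @param spec a [phantom_spec()].
#' @param n_theta,n_z surface tessellation (defaults 96 x 80 for skin).
#' @return List of class `phantom`: `skin` and `bone` (closed `tri_mesh`es,
#'   outward-oriented), `landmarks` (ridge-apex coordinates, one per ridge,
#'   usable as coarse-registration features), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), n_theta = 96L, n_z = 80L) {
  stopifnot(inherits(spec, "phantom_spec"))
  skin_xy <- function(theta, z) {
    ax <- .phantom_axes(spec, z)
    h <- .ridge_height_at(spec, theta, z)
    cbind((ax[, 1] + h) * cos(theta), (ax[, 2] + h) * sin(theta))
  }
  skin <- .parametric_tube(skin_xy, 0, spec$length, n_theta, n_z)
  bz <- .bone_z_range(spec)
  bone_xy <- function(phi, z) {
    r <- .bone_radius_at(spec, phi, z)
    cbind(spec$bone_offset[1] + r * cos(phi), spec$bone_offset[2] + r * sin(phi))
  }
  bone <- .parametric_tube(bone_xy, bz[1], bz[2], max(48L, n_theta %/% 2L),
                           max(40L, n_z %/% 2L))
  rid <- .phantom_ridges(spec)
  landmarks <- if (nrow(rid) > 0) {
    ax <- .phantom_axes(spec, rid[, 2])
    h <- numeric(nrow(rid))
    for (i in seq_len(nrow(rid)))
      h[i] <- .ridge_height_at(spec, rid[i, 1], rid[i, 2])
    cbind((ax[, 1] + h) * cos(rid[, 1]), (ax[, 2] + h) * sin(rid[, 1]), rid[, 2])
  } else matrix(numeric(0), 0, 3)
  # clearance: bone must sit strictly inside the skin
  clearance <- min(nearest_distances(bone$vertices, skin))
  if (clearance <= 2)
    stop(sprintf("bone-to-skin clearance %.2f mm violates the 2 mm minimum", clearance))
  structure(list(skin = skin, bone = bone, landmarks = landmarks, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: skin %d faces, bone %d faces, %d landmarks\n",
              nrow(x$skin$faces), nrow(x$bone$faces), nrow(x$landmarks)))
  invisible(x)
}

#' Analytic phantom membership (ground truth for segmentation tests)
#'
#' Evaluates whether world points lie inside the skin or bone of the analytic
#' phantom shape, independently of any mesh or voxel processing.
#'
#' @param spec a [phantom_spec()].
#' @param points n x 3 matrix, mm.
#' @param what `"skin"` or `"bone"`.
#' @return Logical vector.
#' @export
phantom_inside <- function(spec, points, what = c("skin", "bone")) {
  what <- match.arg(what)
  pts <- .as_xyz_matrix(points)
  z <- pts[, 3]
  if (what == "bone") {
    bz <- .bone_z_range(spec)
    dx <- pts[, 1] - spec$bone_offset[1]; dy <- pts[, 2] - spec$bone_offset[2]
    phi <- atan2(dy, dx)
    r <- .bone_radius_at(spec, phi, z)
    return(z >= bz[1] & z <= bz[2] & dx^2 + dy^2 <= r^2)
  }
  ok <- z >= 0 & z <= spec$length
  ax <- .phantom_axes(spec, pmin(pmax(z, 0), spec$length))
  theta <- atan2(pts[, 2] / ax[, 2], pts[, 1] / ax[, 1])
  h <- .ridge_height_at(spec, theta, z)
  ok & (pts[, 1] / (ax[, 1] + h))^2 + (pts[, 2] / (ax[, 2] + h))^2 <= 1
}

#' Voxelize phantom meshes into a CT-like volume
#'
#' Scanline parity voxelization of the closed skin and bone meshes. Voxels
#' outside the skin are air (-1000 HU), inside the skin 40 HU (soft tissue),
#' inside the bone 700 HU, so the clinical threshold presets (-650 and
#' 125 HU) recover the two structures.
#'
#' @param skin,bone closed `tri_mesh`es (bone inside skin).
#' @param spacing voxel size, mm (scalar or length 3).
#' @param margin empty margin around the skin, voxels (default 3).
#' @return An [hu_volume()].
#' @export
voxelize_ct <- function(skin, bone, spacing = 1, margin = 3L) {
  stopifnot(inherits(skin, "tri_mesh"), inherits(bone, "tri_mesh"))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  lo <- apply(skin$vertices, 2, min) - margin * spacing
  hi <- apply(skin$vertices, 2, max) + margin * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  inside_skin <- cpp_voxelize_mesh(skin$vertices, skin$faces - 1L, dims, spacing, lo)
  inside_bone <- cpp_voxelize_mesh(bone$vertices, bone$faces - 1L, dims, spacing, lo)
  if (!any(inside_skin)) stop("skin mesh voxelized to nothing; is it closed?")
  vals <- array(-1000, dims)
  vals[inside_skin] <- 40
  vals[inside_bone] <- 700
  hu_volume(vals, spacing = spacing, origin = lo)
}

#' Structured-light camera specification
#'
#' A pinhole stand-in for the SLI module: the projector-camera decoding is
#' not simulated, only its output (a visible-surface depth map with Gaussian
#' depth noise and random dropout). Default geometry mimics a camera 1.2 m
#' from the scene with a roughly 0.6 m wide field of view.
#'
#' @param position camera center, mm.
#' @param look_at point the optical axis passes through, mm.
#' @param up approximate up direction.
#' @param nx,ny image grid (rays); at least 16 x 16.
#' @param fov_deg horizontal full field of view, degrees; vertical follows
#'   the aspect ratio.
#' @param noise_sigma depth noise SD along the ray, mm.
#' @param dropout fraction of returned points dropped at random, `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A list of class `sli_camera`.
#' @export
sli_camera <- function(position = c(0, -1200, 80), look_at = c(0, 0, 80),
                       up = c(0, 0, 1), nx = 320L, ny = 240L, fov_deg = 29.9,
                       noise_sigma = 0.1, dropout = 0, seed = 0L) {
  if (nx < 16L || ny < 16L) stop("image grid must be at least 16 x 16")
  if (noise_sigma < 0) stop("noise sigma must be non-negative")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(position = as.numeric(position), look_at = as.numeric(look_at),
                 up = as.numeric(up), nx = as.integer(nx), ny = as.integer(ny),
                 fov_deg = fov_deg, noise_sigma = noise_sigma,
                 dropout = dropout, seed = as.integer(seed)),
            class = "sli_camera")
}

.camera_basis <- function(cam) {
  fwd <- .unitize(cam$look_at - cam$position)
  right <- .unitize(c(fwd[2] * cam$up[3] - fwd[3] * cam$up[2],
                      fwd[3] * cam$up[1] - fwd[1] * cam$up[3],
                      fwd[1] * cam$up[2] - fwd[2] * cam$up[1]))
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  rbind(right, up, fwd)
}

#' Simulate a structured-light surface scan
#'
#' Casts one ray per image-grid cell through the pinhole, keeps the first
#' mesh intersection (hidden surfaces are absent, as in a real one-sided
#' scan), perturbs each point along its ray by Gaussian depth noise, and
#' drops a fraction of points at random. Deterministic per camera seed.
#'
#' @param mesh a `tri_mesh` in world (SLI) coordinates.
#' @param cam an [sli_camera()].
#' @return A `point_cloud` of scan points.
#' @export
simulate_sli <- function(mesh, cam = sli_camera()) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cam, "sli_camera"))
  basis <- .camera_basis(cam)
  tan_x <- tan(cam$fov_deg * pi / 360)
  tan_y <- tan_x * cam$ny / cam$nx
  res <- cpp_raycast(mesh$vertices, mesh$faces - 1L, cam$position, basis,
                     tan_x, tan_y, cam$nx, cam$ny)
  hit <- which(res$hit)
  if (length(hit) == 0L) stop("no ray hits the mesh; adjust camera or field of view")
  pts <- res$point[hit, , drop = FALSE]
  dirs <- res$dir[hit, , drop = FALSE]
  .with_seed(cam$seed, {
    if (cam$noise_sigma > 0)
      pts <- pts + dirs * rnorm(length(hit), sd = cam$noise_sigma)
    if (cam$dropout > 0) {
      n_drop <- round(cam$dropout * nrow(pts))
      if (n_drop > 0) pts <- pts[-sample.int(nrow(pts), n_drop), , drop = FALSE]
    }
    pts
  })
  point_cloud(pts)
}

#' Generate a partial guiding-tube scan cloud
#'
#' Samples the visible angular sector of a cylinder surface (a real scan sees
#' roughly half the circumference), adds radial Gaussian noise, and mixes in
#' outliers uniform over the cylinder's bounding box. True inlier flags are
#' returned for scoring RANSAC fits.
#'
#' @param tube a [cylinder_model()].
#' @param angular_coverage visible sector, degrees in (0, 360].
#' @param n total point count (>= 10).
#' @param noise_sigma radial noise SD, mm.
#' @param outlier_fraction fraction of `n` replaced by outliers, `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A `point_cloud` with attribute `inlier` (logical vector).
#' @export
make_tube_cloud <- function(tube, angular_coverage = 180, n = 2000L,
                            noise_sigma = 0.2, outlier_fraction = 0, seed = 0L) {
  stopifnot(inherits(tube, "cylinder_model"))
  if (angular_coverage <= 0 || angular_coverage > 360)
    stop("angular_coverage must be in (0, 360]")
  if (n < 10L) stop("need at least 10 points")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  n_out <- round(outlier_fraction * n)
  n_in <- n - n_out
  B <- .plane_basis(tube$axis)
  half <- angular_coverage * pi / 360
  .with_seed(seed, {
    th <- runif(n_in, -half, half)
    ax_pos <- runif(n_in, -tube$length / 2, tube$length / 2)
    r <- tube$radius + rnorm(n_in, sd = noise_sigma)
    pts_in <- sweep(r * cos(th) %o% B[, 1] + r * sin(th) %o% B[, 2] +
                    ax_pos %o% tube$axis, 2, tube$center, "+")
    if (n_out > 0) {
      lo <- apply(pts_in, 2, min) - tube$radius
      hi <- apply(pts_in, 2, max) + tube$radius
      pts_out <- cbind(runif(n_out, lo[1], hi[1]), runif(n_out, lo[2], hi[2]),
                       runif(n_out, lo[3], hi[3]))
    } else pts_out <- matrix(numeric(0), 0, 3)
    cloud <- point_cloud(rbind(pts_in, pts_out))
    attr(cloud, "inlier") <- c(rep(TRUE, n_in), rep(FALSE, n_out))
    cloud
  })
}

#' Inject known surface and bone drift into a phantom
#'
#' The "postoperative" skin is the skin moved by `surface_shift`; the bone
#' additionally moves by `extra_bone_shift` (applied in phantom coordinates
#' before the surface shift), emulating skeletal drift exceeding surface
#' drift under puncture forces. The ground truth is returned for recovery
#' tests.
#'
#' @param skin,bone `tri_mesh`es (preoperative phantom).
#' @param surface_shift [rigid_transform()] of the whole specimen.
#' @param extra_bone_shift extra [rigid_transform()] of the bone alone.
#' @return List: `skin`, `bone` (shifted meshes), `truth` (the two
#'   transforms and the bone-shift magnitude at the bone centroid, mm).
#' @export
inject_drift <- function(skin, bone, surface_shift = rigid_transform(),
                         extra_bone_shift = rigid_transform()) {
  stopifnot(inherits(skin, "tri_mesh"), inherits(bone, "tri_mesh"))
  bone_total <- compose_transforms(extra_bone_shift, surface_shift)
  centroid <- colMeans(bone$vertices)
  moved <- apply_transform(matrix(centroid, 1), extra_bone_shift)
  structure(list(skin = apply_transform(skin, surface_shift),
                 bone = apply_transform(bone, bone_total),
                 truth = list(surface_shift = surface_shift,
                              extra_bone_shift = extra_bone_shift,
                              bone_total = bone_total,
                              bone_shift_magnitude = sqrt(sum((moved - centroid)^2)))),
            class = "drift_injection")
}
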