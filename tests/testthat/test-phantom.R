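# Synthetic phantom generators: determinism, geometry, scan simulation.

test_that("make_phantom is deterministic and returns the requested landmarks", {
  a <- make_phantom(phantom_spec(seed = 0))
  b <- make_phantom(phantom_spec(seed = 0))
  expect_identical(a$skin$vertices, b$skin$vertices)
  expect_identical(a$bone$faces, b$bone$faces)
  expect_identical(a$landmarks, b$landmarks)
  expect_equal(nrow(a$landmarks), 6)
  c6 <- make_phantom(phantom_spec(ridge_count = 4, seed = 1))
  expect_equal(nrow(c6$landmarks), 4)
  # different seed jitters ridge placement
  d <- make_phantom(phantom_spec(seed = 2))
  expect_false(identical(a$landmarks, d$landmarks))
})

test_that("bone sits strictly inside the skin with clearance", {
  ph <- make_phantom(phantom_spec(seed = 0))
  d <- nearest_distances(ph$bone$vertices, ph$skin)
  expect_gt(min(d), 2)
  expect_true(all(phantom_inside(ph$spec, ph$bone$vertices, "skin")))
  expect_error(make_phantom(phantom_spec(bone_radius = 40, seed = 0)), "clearance")
})

test_that("voxelized CT recovers skin and bone via the clinical presets", {
  fx <- phantom_fixture()
  vol <- fx$volume
  expect_setequal(unique(as.vector(vol$values)), c(-1000, 40, 700))
  g <- punctnav:::.voxel_centers(dim(vol$values), vol$spacing, vol$origin)
  dice <- function(mask, truth) 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  skin_mask <- as.vector(threshold_preset(vol, "surface")$values)
  bone_mask <- as.vector(threshold_preset(vol, "skeleton")$values)
  expect_gte(dice(skin_mask, phantom_inside(fx$phantom$spec, g, "skin")), 0.98)
  expect_gte(dice(bone_mask, phantom_inside(fx$phantom$spec, g, "bone")), 0.98)
  # no voxel is both air and bone
  expect_equal(sum(vol$values == -1000 & vol$values == 700), 0)
  expect_true(all(skin_mask[bone_mask]))
})

test_that("simulated scans lie on the visible hemisphere of a sphere", {
  # unit-sphere-like mesh: voxelized ball of radius 20
  n <- 45; ctr <- c(22, 22, 22); r <- 20
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  ball <- extract_surface(binary_mask(array(colSums((t(g) - ctr)^2) <= r^2,
                                            c(n, n, n))))
  cam <- sli_camera(position = ctr + c(0, -500, 0), look_at = ctr,
                    nx = 64L, ny = 64L, fov_deg = 12, noise_sigma = 0, seed = 1)
  scan <- simulate_sli(ball, cam)
  # every point on the mesh surface (exactly: distance 0 to the mesh)
  expect_lt(max(nearest_distances(scan, ball)), 1e-6)
  # camera-facing side only: y below the center plane (with voxel tolerance)
  expect_true(all(scan$points[, 2] <= ctr[2] + 1))

  # determinism and dropout count
  cam_d <- sli_camera(position = ctr + c(0, -500, 0), look_at = ctr,
                      nx = 64L, ny = 64L, fov_deg = 12, noise_sigma = 0.1,
                      dropout = 0.5, seed = 2)
  s1 <- simulate_sli(ball, cam_d)
  s2 <- simulate_sli(ball, cam_d)
  expect_identical(s1$points, s2$points)
  expect_equal(n_points(s1), n_points(scan) - round(0.5 * n_points(scan)))
  cam_e <- sli_camera(position = ctr + c(0, -500, 0), look_at = ctr,
                      nx = 64L, ny = 64L, fov_deg = 12, noise_sigma = 0.1,
                      dropout = 0.5, seed = 3)
  expect_false(identical(simulate_sli(ball, cam_e)$points, s1$points))
  expect_error(simulate_sli(ball, sli_camera(position = c(0, -5000, 0),
                                             look_at = c(0, -6000, 0),
                                             fov_deg = 5)),
               "no ray")
})

test_that("tube clouds honor coverage, counts and flags", {
  tube <- cylinder_model(c(0, 0, 0), c(0, 0, 1), 5, 80)
  cl <- make_tube_cloud(tube, angular_coverage = 360, n = 500, noise_sigma = 0,
                        seed = 1)
  d <- punctnav:::.dist_to_axis(cl$points, tube$center, tube$axis)
  expect_lt(max(abs(d - 5)), 1e-9)
  cl_o <- make_tube_cloud(tube, angular_coverage = 180, n = 2000,
                          noise_sigma = 0.2, outlier_fraction = 0.25, seed = 2)
  expect_equal(sum(!attr(cl_o, "inlier")), 500)
  expect_equal(n_points(cl_o), 2000)
  expect_error(make_tube_cloud(tube, angular_coverage = 0), "angular_coverage")
  expect_error(make_tube_cloud(tube, n = 5), "at least 10")
})

test_that("inject_drift shifts meshes and records the ground truth", {
  ph <- make_phantom(phantom_spec(seed = 0))
  none <- inject_drift(ph$skin, ph$bone)
  expect_identical(none$skin$vertices, ph$skin$vertices)
  expect_identical(none$bone$vertices, ph$bone$vertices)

  inj <- inject_drift(ph$skin, ph$bone,
                      surface_shift = translation_transform(c(1, 0, 0)),
                      extra_bone_shift = translation_transform(c(0.3, 0, 0)))
  expect_equal(inj$truth$bone_shift_magnitude, 0.3, tolerance = 1e-12)
  # surface moved by exactly the surface shift
  expect_equal(inj$skin$vertices, ph$skin$vertices + rep(c(1, 0, 0), each = nrow(ph$skin$vertices)))
  # bone moved by surface + extra
  expect_equal(inj$bone$vertices,
               ph$bone$vertices + rep(c(1.3, 0, 0), each = nrow(ph$bone$vertices)))
  # surface-shift-only case: no residual bone drift
  only_surf <- inject_drift(ph$skin, ph$bone,
                            surface_shift = translation_transform(c(0, 2, 0)))
  rep0 <- skeletal_drift(ph$bone, only_surf$bone,
                         only_surf$truth$surface_shift, metric = "point_to_point")
  expect_lt(rep0$mean, 1e-12)
})
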