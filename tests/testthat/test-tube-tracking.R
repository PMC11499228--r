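# Normal estimation, RANSAC cylinder fitting, path-deviation scoring.

std_tube <- cylinder_model(c(10, 20, 30), c(1, 2, 0.5) / sqrt(sum(c(1, 2, 0.5)^2)),
                           radius = 5, length = 80)

test_that("normals on a plane and a cylinder match analytic directions", {
  set.seed(1)
  plane <- point_cloud(cbind(runif(200, -10, 10), runif(200, -10, 10), 0))
  pn <- estimate_normals(plane, k = 6)
  expect_true(all(abs(abs(pn$normals[, 3]) - 1) < 1e-6))

  # regularly sampled cylinder of radius 10 (a scan grid is near-regular)
  ax <- std_tube$axis
  B <- punctnav:::.plane_basis(ax)
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  zz <- seq(-30, 30, length.out = 60)
  g <- expand.grid(th = th, z = zz)
  pts <- sweep(10 * cos(g$th) %o% B[, 1] + 10 * sin(g$th) %o% B[, 2] +
               g$z %o% ax, 2, std_tube$center, "+")
  cn <- estimate_normals(point_cloud(pts), k = 12)
  # analytic normal: radial direction from the axis
  rel <- sweep(pts, 2, std_tube$center)
  proj <- as.numeric(rel %*% ax)
  radial <- rel - proj %o% ax
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(cn$normals * radial)))) * 180 / pi
  expect_lt(max(ang), 2)
  # irregular random sampling keeps the bulk accurate (tails are wider)
  cl <- make_tube_cloud(std_tube, angular_coverage = 360, n = 3000,
                        noise_sigma = 0, seed = 2)
  cr <- estimate_normals(cl, k = 12)
  rel2 <- sweep(cl$points, 2, std_tube$center)
  rad2 <- rel2 - as.numeric(rel2 %*% ax) %o% ax
  rad2 <- rad2 / sqrt(rowSums(rad2^2))
  ang2 <- acos(pmin(1, abs(rowSums(cr$normals * rad2)))) * 180 / pi
  expect_lt(median(ang2), 5)

  expect_error(estimate_normals(plane, k = 2), "at least 3")
  expect_error(estimate_normals(point_cloud(matrix(rnorm(15), 5)), k = 12), "k\\+1")
})

test_that("RANSAC recovers an exact cylinder to numerical precision", {
  cl <- make_tube_cloud(std_tube, angular_coverage = 360, n = 2000,
                        noise_sigma = 0, seed = 3)
  fit <- fit_cylinder_ransac(cl, ransac_params(seed = 1))
  expect_lt(abs(fit$model$radius - 5), 1e-6)
  expect_lt(acos(abs(sum(fit$model$axis * std_tube$axis))) * 180 / pi, 0.01)
  expect_lt(abs(fit$model$length - 80), 0.5)
})

test_that("RANSAC stays accurate under noise and outliers; flags are consistent", {
  cl <- make_tube_cloud(std_tube, angular_coverage = 180, n = 2000,
                        noise_sigma = 0.2, outlier_fraction = 0.25, seed = 4)
  p <- ransac_params(distance_threshold = 0.6, seed = 4)
  fit <- fit_cylinder_ransac(cl, p)
  expect_lt(abs(fit$model$radius - 5), 0.1)
  expect_lt(acos(abs(sum(fit$model$axis * std_tube$axis))) * 180 / pi, 1)
  expect_gte(mean(fit$inliers == attr(cl, "inlier")), 0.95)
  # re-scoring the returned model reproduces the returned flags exactly
  d <- punctnav:::.dist_to_axis(cl$points, fit$model$center, fit$model$axis)
  expect_identical(abs(d - fit$model$radius) <= p$distance_threshold, fit$inliers)
})

test_that("an all-outlier cloud fails the consensus gate", {
  set.seed(5)
  junk <- point_cloud(matrix(runif(600, -50, 50), ncol = 3))
  expect_error(fit_cylinder_ransac(junk, ransac_params(min_inlier_fraction = 0.5,
                                                       seed = 5)),
               "fit failed")
})

test_that("cylinder fit is equivariant under rigid motion of the cloud", {
  cl <- make_tube_cloud(std_tube, angular_coverage = 200, n = 1500,
                        noise_sigma = 0, seed = 6)
  p <- ransac_params(seed = 7)
  fit0 <- fit_cylinder_ransac(cl, p)
  g <- random_rigid(123, max_angle = 40, max_shift = 40)
  fit_g <- fit_cylinder_ransac(apply_transform(cl, g), p)
  expect_lt(abs(fit_g$model$radius - fit0$model$radius), 1e-6)
  expect_lt(abs(fit_g$model$length - fit0$model$length), 1e-5)
  ax_g <- as.numeric(g$rotation %*% fit0$model$axis)
  expect_lt(acos(pmin(1, abs(sum(fit_g$model$axis * ax_g)))) * 180 / pi, 1e-4)
  ctr_g <- as.numeric(apply_transform(matrix(fit0$model$center, 1), g))
  # center may slide along the axis only by numerical amounts
  expect_lt(sqrt(sum((fit_g$model$center - ctr_g)^2)), 1e-4)
})

test_that("radius error grows monotonically with noise", {
  med_err <- vapply(c(0, 0.1, 0.3), function(sig) {
    errs <- vapply(1:20, function(s) {
      cl <- make_tube_cloud(std_tube, angular_coverage = 180, n = 1200,
                            noise_sigma = sig, seed = s)
      fit <- fit_cylinder_ransac(cl, ransac_params(seed = s))
      abs(fit$model$radius - 5)
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) >= -1e-9))
})

test_that("path deviation matches constructed geometry and is flip-symmetric", {
  path <- plan_path(c(0, 0, 0), c(0, 0, 40))
  aligned <- cylinder_model(c(0, 0, 20), c(0, 0, 1), 5, 40)
  dev <- path_deviation(aligned, path)
  expect_equal(dev$angle, 0, tolerance = 1e-9)
  expect_equal(dev$lateral_offset, 0, tolerance = 1e-9)
  expect_equal(dev$tip_gap, 0, tolerance = 1e-9)

  # tilt 10 degrees about an axis through the entry point
  rot <- rotation_transform("x", 10)
  tilted_axis <- as.numeric(rot$rotation %*% c(0, 0, 1))
  tilted <- cylinder_model(20 * tilted_axis, tilted_axis, 5, 40)
  dev_t <- path_deviation(tilted, path)
  expect_equal(dev_t$angle, 10, tolerance = 1e-6)
  expect_equal(dev_t$lateral_offset, 0, tolerance = 1e-9)

  # 3 mm perpendicular offset of an otherwise aligned tube
  shifted <- cylinder_model(c(3, 0, 20), c(0, 0, 1), 5, 40)
  dev_s <- path_deviation(shifted, path)
  expect_equal(dev_s$lateral_offset, 3, tolerance = 1e-9)

  # flipping the axis sign changes nothing
  flipped <- cylinder_model(shifted$center, -shifted$axis, 5, 40)
  dev_f <- path_deviation(flipped, path)
  expect_equal(dev_f$angle, dev_s$angle)
  expect_equal(dev_f$lateral_offset, dev_s$lateral_offset)
  expect_equal(dev_f$tip_gap, dev_s$tip_gap)
})

test_that("tolerance gate is inclusive at the boundary and names violations", {
  ok <- structure(list(angle = 0, lateral_offset = 0, tip_gap = 0),
                  class = "path_deviation")
  expect_true(check_tolerance(ok, 3, 2)$pass)
  bad <- structure(list(angle = 5, lateral_offset = 0, tip_gap = 0),
                   class = "path_deviation")
  res <- check_tolerance(bad, 3, 2)
  expect_false(res$pass)
  expect_match(res$message, "angle")
  border <- structure(list(angle = 3, lateral_offset = 2, tip_gap = 0),
                      class = "path_deviation")
  expect_true(check_tolerance(border, 3, 2)$pass)
  expect_error(check_tolerance(ok, -1, 2), "positive")
})

test_that("cylinder meshes enclose the analytic volume", {
  m <- cylinder_mesh(std_tube, n_segments = 128L)
  expect_lt(abs(mesh_volume(m) / (pi * 25 * 80) - 1), 0.01)
  path <- plan_path(c(0, 0, 0), c(0, 0, 40))
  pm <- cylinder_mesh(path, radius = 2, n_segments = 64L)
  expect_lt(abs(mesh_volume(pm) / (pi * 4 * 40) - 1), 0.01)
})
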