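# Landmark alignment, trimmed ICP, the two-step registration, and cropping.

test_that("coarse_align recovers known transforms and handles degeneracy", {
  lm <- random_cloud(1, n = 5, scale = 40)$points
  expect_transform_equal(coarse_align(lm, lm), rigid_transform())
  for (s in 1:10) {
    t <- random_rigid(s + 10)
    expect_transform_equal(coarse_align(lm, apply_transform(lm, t)), t, tol = 1e-9)
  }
  expect_error(coarse_align(lm[1:2, ], lm[1:2, ]), "3 landmark")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(coarse_align(line, line), "collinear")
  expect_error(coarse_align(lm, lm[1:4, ]), "equal length")
})

test_that("coarse_align residual stays within the noise bound", {
  lm <- random_cloud(2, n = 4, scale = 40)$points
  rms_resid <- vapply(1:100, function(s) {
    t <- random_rigid(s + 500)
    set.seed(s)
    noisy <- apply_transform(lm, t) + matrix(rnorm(12, sd = 0.1), ncol = 3)
    est <- coarse_align(lm, noisy)
    sqrt(mean(rowSums((apply_transform(lm, est) - noisy)^2)))
  }, 0)
  expect_lt(max(rms_resid), 3 * 0.1)
})

test_that("ICP self-alignment converges immediately and the trace is monotone", {
  fx <- phantom_fixture()
  scan <- simulate_sli(fx$phantom$skin, facing_camera(fx$phantom$skin))
  res <- icp_refine(scan, fx$phantom$skin, p = icp_params(subsample_size = 1500, seed = 1))
  expect_lt(res$rms, 1e-6)
  expect_lte(res$iterations, 2)
  expect_true(res$converged)
  expect_true(all(diff(res$rms_trace) <= 1e-9))
})

test_that("ICP recovers a small pose perturbation on noiseless data", {
  fx <- phantom_fixture()
  mesh <- fx$phantom$skin
  scan <- simulate_sli(mesh, facing_camera(mesh))
  pose <- rotation_transform(c(0.1, 1, 0.2), 4, c(3, 2, -4))  # <=5 deg, <=5 mm
  moved <- apply_transform(scan, pose)   # scan in "SLI" pose
  init <- compose_transforms(invert_transform(pose),
                             rotation_transform("z", 1, c(0.5, 0, 0)))
  res <- icp_refine(moved, mesh, init = init,
                    p = icp_params(subsample_size = 1500, seed = 2))
  back <- apply_transform(moved, res$total)
  expect_lt(rms(nearest_distances(back, mesh)), 0.05)

  # the classic point-to-point variant keeps a monotone error trace
  res_pp <- icp_refine(moved, mesh, init = init,
                       p = icp_params(subsample_size = 1500, seed = 2,
                                      metric = "point_to_point",
                                      max_iterations = 40))
  expect_true(all(diff(res_pp$rms_trace) <= 1e-9))
})

test_that("trimming rescues ICP from planted outliers; no trimming fails", {
  fx <- phantom_fixture()
  mesh <- fx$phantom$skin
  scan <- simulate_sli(mesh, facing_camera(mesh))
  set.seed(3)
  n <- n_points(scan)
  n_out <- round(0.2 * n)
  out_idx <- sample.int(n, n_out)
  pts <- scan$points
  pts[out_idx, ] <- pts[out_idx, ] + 50
  corrupted <- point_cloud(pts)
  init <- rotation_transform("y", 2, c(2, -1, 1))
  p_trim <- icp_params(subsample_size = 2000, trim_fraction = 0.3, seed = 4)
  p_none <- icp_params(subsample_size = 2000, trim_fraction = 0, seed = 4)
  res_trim <- icp_refine(corrupted, mesh, init = init, p = p_trim)
  res_none <- icp_refine(corrupted, mesh, init = init, p = p_none)
  clean_after <- function(res) {
    moved <- apply_transform(point_cloud(scan$points), res$total)
    rms(nearest_distances(moved, mesh))
  }
  # the clean points should land back on the surface only with trimming
  expect_lt(clean_after(res_trim), 0.1)
  expect_gt(clean_after(res_none), 0.1)
})

test_that("two-step registration recovers a known pose on the CT model", {
  fx <- phantom_fixture()
  surf <- fx$surface
  pose <- rotation_transform(c(0.2, 0.3, 1), 4, c(3, -4, 2))
  posed <- apply_transform(surf, pose)
  scan <- simulate_sli(posed, facing_camera(posed, noise_sigma = 0, seed = 1))
  lm_src <- fx$phantom$landmarks
  lm <- list(src = lm_src, dst = apply_transform(lm_src, pose))
  res <- register_two_step(scan, surf, lm,
                           icp_params(subsample_size = 2000, seed = 0))
  expect_true(res$converged)
  expect_lt(res$rms, 0.05)
  probe <- surf$vertices[seq(1, nrow(surf$vertices), length.out = 400), ]
  err <- apply_transform(probe, res$total) - apply_transform(probe, pose)
  expect_lt(rms(sqrt(rowSums(err^2))), 0.05)
  # total composes fine before coarse: R = R_FM %*% R_ICP
  expect_transform_equal(res$total, compose_transforms(res$fine, res$coarse),
                         tol = 1e-9)
  expect_error(register_two_step(scan, surf,
                                 list(src = lm$src, dst = lm$dst[1:3, ]),
                                 icp_params(subsample_size = 500)),
               "equal length")
})

test_that("two-step registration is equivariant under a global rigid motion", {
  fx <- phantom_fixture()
  surf <- fx$surface
  pose <- rotation_transform("z", 3, c(2, 1, -1))
  posed <- apply_transform(surf, pose)
  scan <- simulate_sli(posed, facing_camera(posed, noise_sigma = 0, seed = 5))
  lm <- list(src = fx$phantom$landmarks,
             dst = apply_transform(fx$phantom$landmarks, pose))
  p <- icp_params(subsample_size = 1500, seed = 6)
  res0 <- register_two_step(scan, surf, lm, p)
  g <- random_rigid(99, max_angle = 30, max_shift = 30)
  res_g <- register_two_step(apply_transform(scan, g), surf,
                             list(src = lm$src, dst = apply_transform(lm$dst, g)), p)
  expect_transform_equal(res_g$total, compose_transforms(res0$total, g), tol = 1e-6)
})

test_that("registration accuracy degrades monotonically with scan noise", {
  fx <- phantom_fixture()
  mesh <- fx$phantom$skin
  pose <- rotation_transform("x", 3, c(2, -2, 3))
  posed <- apply_transform(mesh, pose)
  lm <- list(src = fx$phantom$landmarks,
             dst = apply_transform(fx$phantom$landmarks, pose))
  probe <- mesh$vertices[seq(1, nrow(mesh$vertices), length.out = 300), ]
  med_err <- vapply(c(0, 0.1, 0.3, 0.5), function(sig) {
    errs <- vapply(1:5, function(s) {
      scan <- simulate_sli(posed, facing_camera(posed, noise_sigma = sig, seed = s))
      res <- register_two_step(scan, mesh, lm,
                               icp_params(subsample_size = 1200, max_iterations = 40,
                                          seed = s))
      err <- apply_transform(probe, res$total) - apply_transform(probe, pose)
      rms(sqrt(rowSums(err^2)))
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) >= -1e-6))
})

test_that("crop_and_denoise filters by box and isolation", {
  cl <- random_cloud(7, n = 400, scale = 5)
  # fully inside a generous box, no outliers: unchanged
  big_box <- rbind(rep(-100, 3), rep(100, 3))
  expect_equal(n_points(crop_and_denoise(cl, big_box, sigma_factor = 1e6)),
               400)
  # 10 mutually isolated points ~100+ mm away are removed
  set.seed(71)
  iso <- matrix(runif(30, 80, 200), ncol = 3)
  mixed <- point_cloud(rbind(cl$points, iso))
  filtered <- crop_and_denoise(mixed, nn_k = 8, sigma_factor = 2)
  expect_equal(n_points(filtered), 400)
  expect_lt(max(nearest_distances(filtered, cl)), 1e-12)
  # half-space crop matches a brute-force bound count
  ctr <- colMeans(cl$points)
  half_box <- rbind(c(ctr[1], -Inf, -Inf), rep(Inf, 3))
  kept <- crop_and_denoise(cl, half_box, sigma_factor = 1e6)
  expect_equal(n_points(kept), sum(cl$points[, 1] >= ctr[1]))
  # empty crop errors
  expect_error(crop_and_denoise(cl, rbind(c(1e5, 1e5, 1e5), c(2e5, 2e5, 2e5))),
               "excludes")
})
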