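# Drift quantification and cohort statistics.

test_that("drift_field handles identity, planes and matches brute force", {
  mesh <- plane_mesh(z0 = 0)
  self <- drift_field(mesh, mesh)
  expect_equal(self$rms, 0)
  expect_equal(self$max, 0)

  above <- plane_mesh(z0 = 0.5, half = 10)
  rep05 <- drift_field(above, mesh)
  expect_equal(rep05$rms, 0.5, tolerance = 1e-12)
  expect_equal(rep05$sd, 0, tolerance = 1e-12)

  moving <- random_mesh(1, n_vert = 40, n_face = 50)
  reference <- random_mesh(2, n_vert = 50, n_face = 70)
  t <- random_rigid(3, max_angle = 20, max_shift = 5)
  rep_r <- drift_field(moving, reference, t)
  moved <- apply_transform(moving, t)
  bf <- brute_mesh_distances(moved$vertices, reference)
  expect_equal(rep_r$distances, bf, tolerance = 1e-9)
  expect_equal(rep_r$rms, sqrt(mean(bf^2)), tolerance = 1e-12)
  expect_equal(rep_r$mean, mean(bf), tolerance = 1e-12)
  expect_equal(rep_r$max, max(bf), tolerance = 1e-12)
})

test_that("drift rms is invariant under a common rigid motion", {
  moving <- random_mesh(4, n_vert = 40, n_face = 50)
  reference <- random_mesh(5, n_vert = 50, n_face = 70)
  base <- drift_field(moving, reference)
  g <- random_rigid(6)
  both <- drift_field(apply_transform(moving, g), apply_transform(reference, g))
  expect_equal(both$rms, base$rms, tolerance = 1e-9)
})

test_that("skeletal drift recovers constructed displacements", {
  fx <- phantom_fixture()
  bone <- fx$phantom$bone
  align <- random_rigid(7, max_angle = 10, max_shift = 10)
  # post = pre under the surface alignment: residual is zero
  post_same <- apply_transform(bone, align)
  expect_lt(skeletal_drift(bone, post_same, align)$rms, 1e-9)
  # extra 0.3 mm shift: corresponding-vertex residual is exactly 0.3
  post_shift <- apply_transform(post_same, translation_transform(c(0.3, 0, 0)))
  rep_s <- skeletal_drift(bone, post_shift, align, metric = "point_to_point")
  expect_equal(rep_s$mean, 0.3, tolerance = 1e-6)
  expect_equal(rep_s$sd, 0, tolerance = 1e-6)
  # planar bone under a normal shift: point-to-mesh also sees exactly 0.3
  plate <- plane_mesh(z0 = 0, half = 10)
  plate_post <- apply_transform(plate, translation_transform(c(0, 0, 0.3)))
  expect_equal(drift_field(plate, plate_post)$mean, 0.3, tolerance = 1e-9)
})

test_that("cohort_summary matches a two-pass oracle and the specimen table", {
  set.seed(8)
  x <- rnorm(37, 0.4, 0.2)
  cs <- cohort_summary(x)
  mean2 <- sum(x) / length(x)
  var2 <- sum((x - mean2)^2) / (length(x) - 1)
  expect_equal(cs$mean, mean2, tolerance = 1e-12)
  expect_equal(cs$sd, sqrt(var2), tolerance = 1e-12)

  df <- read_drift_table()
  expect_equal(nrow(df), 20)
  s <- summarize_drift_table(df)
  # printed column summaries, to the printed precision (rows are printed
  # rounded to 3 decimals, so recomputation can differ by 1 in the last digit)
  expect_lt(abs(s$columns$rms_ct_sli$mean - 0.576), 1e-3)
  expect_lt(abs(s$columns$rms_ct_sli$sd - 0.146), 1e-3)
  expect_lt(abs(s$columns$rms_ct_ct$mean - 0.407), 1e-3)
  expect_lt(abs(s$columns$rms_ct_ct$sd - 0.234), 1e-3)
  expect_lt(abs(s$columns$skeletal_drift$mean - 0.235), 1e-3)
  expect_lt(abs(s$columns$skeletal_drift$sd - 0.197), 1e-3)
  expect_lt(abs(s$columns$surface_drift$mean - 0.033), 1e-3)
  # the surface-drift SD recomputed from the rows is ~0.027, far from the
  # printed 0.272 (an order-of-magnitude typo in the source table)
  expect_lt(s$columns$surface_drift$sd, 0.05)

  expect_equal(cohort_summary(rep(0.4, 20))$mean, 0.4)
  expect_equal(cohort_summary(rep(0.4, 20))$sd, 0)
  expect_error(cohort_summary(0.4), "at least 2")
})

test_that("paired differences reproduce the cohort comparisons", {
  df <- read_drift_table()
  p1 <- paired_difference(df$rms_ct_ct, df$rms_ct_sli)
  expect_lt(abs(p1$mean - (-0.169)), 1e-3)
  expect_lt(abs(p1$sd - 0.196), 1e-3)
  p2 <- paired_difference(df$skeletal_drift, df$surface_drift)
  expect_lt(abs(p2$mean - 0.202), 1e-3)
  expect_lt(abs(p2$sd - 0.198), 1e-3)
  # linearity against cohort summaries
  expect_equal(p1$mean,
               cohort_summary(df$rms_ct_ct)$mean - cohort_summary(df$rms_ct_sli)$mean,
               tolerance = 1e-12)
  # both paired comparisons are significant at 0.05
  expect_lt(p1$p_value, 0.05)
  expect_lt(p2$p_value, 0.05)
  # degenerate all-equal case: t undefined
  pe <- paired_difference(df$rms_ct_sli, df$rms_ct_sli)
  expect_equal(pe$mean, 0)
  expect_true(is.na(pe$t))
  expect_error(paired_difference(1:3, 1:4), "equal length")
})

test_that("one-sample t against zero flags nonzero cohorts", {
  df <- read_drift_table()
  for (cn in c("rms_ct_sli", "rms_ct_ct", "surface_drift", "skeletal_drift"))
    expect_lt(t_against_zero(df[[cn]])$p_value, 0.05)
})

test_that("display rounding is half-away-from-zero at 3 decimals", {
  expect_equal(round_half_up(0.5755), 0.576)
  expect_equal(round_half_up(-0.5755), -0.576)
  expect_equal(round_half_up(0.0005), 0.001)
  expect_equal(round_half_up(0.2345), 0.235)
  expect_equal(format(cohort_summary(read_drift_table()$rms_ct_ct)), "0.407 ± 0.234")
})
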