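# Rigid-transform algebra and nearest-distance queries.

test_that("apply_transform matches analytic cases and preserves geometry", {
  cl <- random_cloud(1)
  expect_equal(apply_transform(cl, rigid_transform())$points, cl$points)

  t90 <- rotation_transform("z", 90, c(0, 0, 5))
  expect_equal(as.numeric(apply_transform(matrix(c(1, 0, 0), 1), t90)),
               c(0, 1, 5), tolerance = 1e-12)

  # pairwise distances preserved (brute-force distance matrices)
  t <- random_rigid(2)
  moved <- apply_transform(cl, t)
  expect_lt(max(abs(dist(cl$points) - dist(moved$points))), 1e-9)

  # triangle areas preserved for meshes
  mesh <- random_mesh(3)
  expect_equal(mesh_area(apply_transform(mesh, t)), mesh_area(mesh),
               tolerance = 1e-9)

  # normals rotate without translation and stay unit
  cln <- estimate_normals(random_cloud(4, n = 40), k = 5)
  mn <- apply_transform(cln, t)
  expect_equal(rowSums(mn$normals^2), rep(1, 40), tolerance = 1e-9)
  expect_equal(mn$normals, cln$normals %*% t(t$rotation))
})

test_that("invalid rotations are rejected", {
  expect_error(rigid_transform(matrix(1:9, 3, 3), c(0, 0, 0)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "determinant")
})

test_that("compose and invert satisfy the group laws", {
  for (s in 1:20) {
    t1 <- random_rigid(s); t2 <- random_rigid(s + 100)
    g <- compose_transforms(t1, t2)
    pts <- random_cloud(s + 200, n = 10)$points
    expect_lt(max(abs(apply_transform(apply_transform(pts, t1), t2) -
                      apply_transform(pts, g))), 1e-9)
    expect_transform_equal(compose_transforms(t1, invert_transform(t1)),
                           rigid_transform())
    # associativity
    t3 <- random_rigid(s + 300)
    expect_transform_equal(compose_transforms(compose_transforms(t1, t2), t3),
                           compose_transforms(t1, compose_transforms(t2, t3)))
  }
  t <- random_rigid(7)
  expect_transform_equal(compose_transforms(rigid_transform(), t), t)
  expect_transform_equal(compose_transforms(t, rigid_transform()), t)
  expect_equal(invert_transform(translation_transform(c(0, 0, 3)))$translation,
               c(0, 0, -3))
  # round-trip of points through t then t^-1
  pts <- random_cloud(8, n = 20)$points
  back <- apply_transform(apply_transform(pts, t), invert_transform(t))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("additive legacy composition agrees with exact for pure-translation second step", {
  t1 <- random_rigid(11)
  t2 <- translation_transform(c(0.3, -0.2, 0.15))
  expect_transform_equal(compose_transforms(t1, t2, translation = "exact"),
                         compose_transforms(t1, t2, translation = "additive"))
  # and differs in general when the second rotation is not the identity
  t3 <- random_rigid(12)
  ex <- compose_transforms(t1, t3, translation = "exact")
  ad <- compose_transforms(t1, t3, translation = "additive")
  expect_gt(max(abs(ex$translation - ad$translation)), 1e-6)
})

test_that("nearest distances to a point cloud equal the brute-force oracle", {
  q <- random_cloud(21, n = 200)$points
  tgt <- random_cloud(22, n = 500)$points
  expect_equal(nearest_distances(q, point_cloud(tgt)), brute_nn_distances(q, tgt),
               tolerance = 1e-12)
  # identity case
  expect_equal(nearest_distances(point_cloud(tgt), point_cloud(tgt)),
               rep(0, 500))
})

test_that("nearest distances to a mesh are exact point-to-surface distances", {
  mesh <- plane_mesh(z0 = 0)
  set.seed(31)
  q <- cbind(runif(50, -15, 15), runif(50, -15, 15), 3.5)
  expect_equal(nearest_distances(q, mesh), rep(3.5, 50), tolerance = 1e-12)

  mesh2 <- random_mesh(32, n_vert = 40, n_face = 60)
  q2 <- random_cloud(33, n = 60)$points
  expect_equal(nearest_distances(q2, mesh2), brute_mesh_distances(q2, mesh2),
               tolerance = 1e-9)
  # projecting onto faces can only shorten relative to nearest vertex
  expect_true(all(nearest_distances(q2, mesh2) <=
                  nearest_distances(q2, point_cloud(mesh2$vertices)) + 1e-12))
})

test_that("knn against brute force on small instances", {
  tgt <- random_cloud(41, n = 300)$points
  q <- random_cloud(42, n = 100)$points
  kn <- knn_points(tgt, q, k = 5)
  for (i in c(1, 50, 100)) {
    d <- sort(sqrt(colSums((t(tgt) - q[i, ])^2)))[1:5]
    expect_equal(as.numeric(kn$distance[i, ]), d, tolerance = 1e-12)
  }
  expect_error(nearest_distances(q, matrix(numeric(0), 0, 3)), "empty")
})
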