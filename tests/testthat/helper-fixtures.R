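# Shared fixtures and independent brute-force oracles. Oracles are written
# in plain R, independent of the accelerated paths they check.

random_rigid <- function(seed, max_angle = 180, max_shift = 50) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_transform(ax, runif(1, -max_angle, max_angle),
                     runif(3, -max_shift, max_shift))
}

random_cloud <- function(seed, n = 50, scale = 10) {
  set.seed(seed)
  point_cloud(matrix(rnorm(3 * n, sd = scale), ncol = 3))
}

random_mesh <- function(seed, n_vert = 60, n_face = 80, scale = 10) {
  set.seed(seed)
  V <- matrix(rnorm(3 * n_vert, sd = scale), ncol = 3)
  F <- t(replicate(n_face, sample.int(n_vert, 3)))
  tri_mesh(V, F)
}

# unit square-grid plane mesh at z = z0
plane_mesh <- function(z0 = 0, half = 20, step = 2) {
  xs <- seq(-half, half, by = step)
  grid <- expand.grid(x = xs, y = xs)
  V <- cbind(grid$x, grid$y, z0)
  n <- length(xs)
  id <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  F <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  tri_mesh(V, F)
}

# exact closest point on one triangle (Ericson), R reference implementation
closest_on_triangle_r <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + w * (c - b))
  }
  den <- va + vb + vc
  a + (vb / den) * ab + (vc / den) * ac
}

# brute-force O(N*M) point-to-mesh distances
brute_mesh_distances <- function(q, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  apply(q, 1, function(p) {
    min(apply(F, 1, function(f) {
      cp <- closest_on_triangle_r(p, V[f[1], ], V[f[2], ], V[f[3], ])
      sqrt(sum((p - cp)^2))
    }))
  })
}

# brute-force nearest-neighbour distances between point sets
brute_nn_distances <- function(q, target) {
  apply(q, 1, function(p) min(sqrt(colSums((t(target) - p)^2))))
}

# brute-force 3D flood fill (26- or 6-connectivity) returning component sizes
brute_component_sizes <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, , drop = FALSE]
  cur <- 0L
  sizes <- integer(0)
  idx_all <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    cur <- cur + 1L
    stack <- list(v)
    lab[v[1], v[2], v[3]] <- cur
    count <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      count <- count + 1L
      for (q in seq_len(nrow(nb))) {
        w <- p + nb[q, ]
        if (any(w < 1L) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    sizes <- c(sizes, count)
  }
  sizes
}

# standard test phantom + derived CT models, computed once per test run
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(phantom_spec(seed = 0))
      vol <- voxelize_ct(ph$skin, ph$bone, spacing = 1)
      cache <<- list(phantom = ph, volume = vol,
                     surface = segment_model(vol, "surface"),
                     skeleton = segment_model(vol, "skeleton"))
    }
    cache
  }
})

# camera facing the centroid of a mesh from the -y side at scanner distance
facing_camera <- function(mesh, noise_sigma = 0, seed = 0L, nx = 320L, ny = 240L) {
  ctr <- colMeans(mesh$vertices)
  sli_camera(position = ctr + c(0, -1200, 0), look_at = ctr,
             nx = nx, ny = ny, noise_sigma = noise_sigma, seed = seed)
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
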