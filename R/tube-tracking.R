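## Guiding-tube tracking: estimate per-point normals, fit a cylinder to the
## tube scan by RANSAC (two-point-with-normals minimal sample), and score the
## fitted tube against the planned puncture path. The structured-light camera
## sees roughly half the tube circumference, so all routines tolerate partial
## angular coverage; fits become unstable below about 120 degrees of coverage.

#' RANSAC parameter set for cylinder fitting
#'
#' @param distance_threshold inlier band half-width, mm: a point is an inlier
#'   when `|distance_to_axis - radius| <= distance_threshold` (default 0.6).
#' @param max_iterations minimal-sample draws (default 1000).
#' @param min_inlier_fraction fail the fit below this consensus (default 0.3).
#' @param normal_k neighbours for normal estimation (default 12).
#' @param seed integer RNG seed.
#' @return A list of class `ransac_params`.
#' @export
ransac_params <- function(distance_threshold = 0.6, max_iterations = 1000L,
                          min_inlier_fraction = 0.3, normal_k = 12L, seed = 0L) {
  if (distance_threshold <= 0) stop("distance_threshold must be positive")
  if (max_iterations < 1L) stop("max_iterations must be at least 1")
  structure(list(distance_threshold = distance_threshold,
                 max_iterations = as.integer(max_iterations),
                 min_inlier_fraction = min_inlier_fraction,
                 normal_k = as.integer(normal_k), seed = as.integer(seed)),
            class = "ransac_params")
}

#' Estimate per-point normals from local covariance
#'
#' The normal at a point is the eigenvector of the smallest eigenvalue of the
#' covariance of its k nearest neighbours; signs are oriented toward a
#' viewpoint (the camera position for structured-light scans).
#'
#' @param cloud a `point_cloud` with more than `k` points.
#' @param k neighbourhood size (>= 3).
#' @param viewpoint length-3 mm vector the normals should face; defaults to
#'   far above the cloud centroid along +z.
#' @return The `point_cloud` with unit normals attached.
#' @export
estimate_normals <- function(cloud, k = 12L, viewpoint = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  n <- n_points(cloud)
  if (n < k + 1L) stop("cloud must have at least k+1 points")
  if (is.null(viewpoint))
    viewpoint <- colMeans(cloud$points) + c(0, 0, 1e6)
  kn <- cpp_knn(cloud$points, cloud$points, k + 1L)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- cloud$points[kn$index[i, ], , drop = FALSE]
    cov3 <- crossprod(sweep(nb, 2, colMeans(nb)))
    ev <- eigen(cov3, symmetric = TRUE)
    nv <- ev$vectors[, 3]
    if (sum(nv * (viewpoint - cloud$points[i, ])) < 0) nv <- -nv
    normals[i, ] <- nv
  }
  point_cloud(cloud$points, normals = normals, scalars = cloud$scalars)
}

.dist_to_axis <- function(pts, point_on_axis, axis) {
  rel <- sweep(pts, 2, point_on_axis)
  proj <- rel %*% axis
  sqrt(pmax(rowSums(rel^2) - as.numeric(proj)^2, 0))
}

## Least-squares cylinder refinement over a fixed inlier set: axis direction
## parameterized by spherical angles, axis point by 2 coordinates in the
## plane orthogonal to the initial axis; radius is profiled out (mean radial
## distance is the LS optimum for fixed axis).
## Gauss-Newton on residuals r_i = d_i - mean(d), where d_i is the distance
## of point i to the axis. Parameters per step: 2 axis tilts and 2 in-plane
## axis-point offsets in the frame of the current axis (the radius is
## profiled out as mean(d)). Analytic Jacobian, damped steps, re-centered
## frame each iteration; converges to machine precision on clean data.
.refine_cylinder <- function(pts, axis0, point0) {
  a <- .unitize(axis0); c0 <- point0
  n <- nrow(pts)
  for (it in 1:60) {
    B <- .plane_basis(a)
    w <- sweep(pts, 2, c0)
    t_ax <- as.numeric(w %*% a)
    perp <- w - t_ax %o% a
    d <- sqrt(rowSums(perp^2))
    d_safe <- pmax(d, 1e-12)
    u <- perp / d_safe
    # derivatives of d_i: axis tilt a -> a + eps*B[,k]: dd = -(t_i/d_i)(w_i . B_k)
    # (via d^2 = |w|^2 - t^2, dt = w . da); point shift c -> c + eps*B[,k]:
    # dd = -(u_i . B_k)
    J <- cbind(-(t_ax / d_safe) * (w %*% B[, 1]),
               -(t_ax / d_safe) * (w %*% B[, 2]),
               -(u %*% B[, 1]), -(u %*% B[, 2]))
    r <- d - mean(d)
    Jc <- sweep(J, 2, colMeans(J))      # residuals are centered, so is J
    step <- tryCatch(solve(crossprod(Jc) + 1e-12 * diag(4), -crossprod(Jc, r)),
                     error = function(e) rep(0, 4))
    a_new <- .unitize(a + step[1] * B[, 1] + step[2] * B[, 2])
    c_new <- c0 + step[3] * B[, 1] + step[4] * B[, 2]
    moved <- max(abs(step))
    a <- a_new; c0 <- c_new
    if (moved < 1e-13) break
  }
  d <- .dist_to_axis(pts, c0, a)
  list(axis = a, point = c0, radius = mean(d))
}

.plane_basis <- function(axis) {
  a <- .unitize(axis)
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unitize(h - sum(h * a) * a)
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3], a[1] * u[2] - a[2] * u[1])
  cbind(u, v)
}

#' Fit a cylinder to a tube scan by RANSAC
#'
#' Minimal sample: two points with normals. The candidate axis is the
#' normalized cross product of the two normals (the surface normal of a
#' cylinder is perpendicular to its axis everywhere); the axis point is where
#' the two inward normal lines approach each other in the projected plane,
#' and the radius follows from the mean axis distance of the sample pair.
#' The best-consensus candidate is refined by least squares over its inliers;
#' length and center come from the extent of inlier projections on the axis.
#' Inlier flags are re-scored against the refined model, so flags and model
#' are mutually consistent.
#'
#' @param cloud a `point_cloud`; normals are estimated with `p$normal_k`
#'   neighbours if absent.
#' @param p a [ransac_params()].
#' @param viewpoint optional camera position for normal orientation.
#' @return List of class `cylinder_fit`: `model` ([cylinder_model()]),
#'   `inliers` (logical), `inlier_fraction`, `iterations`.
#' @export
fit_cylinder_ransac <- function(cloud, p = ransac_params(), viewpoint = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(p, "ransac_params"))
  if (is.null(cloud$normals)) cloud <- estimate_normals(cloud, p$normal_k, viewpoint)
  pts <- cloud$points
  nrm <- cloud$normals
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points with normals")

  pairs <- .with_seed(p$seed, {
    cbind(sample.int(n, p$max_iterations, replace = TRUE),
          sample.int(n, p$max_iterations, replace = TRUE))
  })
  best <- NULL
  best_count <- -1L
  for (it in seq_len(p$max_iterations)) {
    i <- pairs[it, 1]; j <- pairs[it, 2]
    if (i == j) next
    ax <- c(nrm[i, 2] * nrm[j, 3] - nrm[i, 3] * nrm[j, 2],
            nrm[i, 3] * nrm[j, 1] - nrm[i, 1] * nrm[j, 3],
            nrm[i, 1] * nrm[j, 2] - nrm[i, 2] * nrm[j, 1])
    axn <- sqrt(sum(ax^2))
    if (axn < 1e-3) next                       # near-parallel normals
    ax <- ax / axn
    # project the two points and their normal lines into the axis-orthogonal
    # plane; the axis pierces that plane where the two lines p - t*n cross
    B <- .plane_basis(ax)
    p2 <- rbind(pts[i, ] %*% B, pts[j, ] %*% B)
    n2 <- rbind(nrm[i, ] %*% B, nrm[j, ] %*% B)
    # solve p1 - t1 n1 = p2 - t2 n2 (2x2 system)
    A <- cbind(-as.numeric(n2[1, ]), as.numeric(n2[2, ]))
    dt <- det(A)
    if (abs(dt) < 1e-9) next
    tt <- solve(A, as.numeric(p2[2, ] - p2[1, ]))
    c2 <- as.numeric(p2[1, ]) - tt[1] * as.numeric(n2[1, ])
    center_plane <- as.numeric(B %*% c2)
    # lift to 3D: any point with the same in-plane coordinates lies on the axis
    radius <- mean(c(sqrt(sum((as.numeric(p2[1, ]) - c2)^2)),
                     sqrt(sum((as.numeric(p2[2, ]) - c2)^2))))
    if (radius < 1e-6) next
    d <- .dist_to_axis(pts, center_plane, ax)
    count <- sum(abs(d - radius) <= p$distance_threshold)
    if (count > best_count) {
      best_count <- count
      best <- list(axis = ax, point = center_plane, radius = radius)
    }
  }
  if (is.null(best) || best_count < p$min_inlier_fraction * n)
    stop(sprintf("cylinder fit failed: best consensus %d/%d below minimum fraction %.2f",
                 max(best_count, 0L), n, p$min_inlier_fraction))

  d <- .dist_to_axis(pts, best$point, best$axis)
  inl <- abs(d - best$radius) <= p$distance_threshold
  ref <- .refine_cylinder(pts[inl, , drop = FALSE], best$axis, best$point)
  # second pass on a robust-scale band: residual-in-band outliers (stray
  # points that happen to fall inside the consensus shell) otherwise bias
  # the radius when the surface noise is comparable to the band width
  resid <- .dist_to_axis(pts, ref$point, ref$axis) - ref$radius
  sc <- stats::mad(resid[abs(resid) <= p$distance_threshold], center = 0)
  band2 <- min(p$distance_threshold, max(2.5 * sc, 1e-9))
  sel2 <- abs(resid) <= band2
  if (sum(sel2) >= 6L)
    ref <- .refine_cylinder(pts[sel2, , drop = FALSE], ref$axis, ref$point)
  # re-score against the refined model
  d <- .dist_to_axis(pts, ref$point, ref$axis)
  inl <- abs(d - ref$radius) <= p$distance_threshold
  if (sum(inl) < p$min_inlier_fraction * n)
    stop("cylinder fit failed after refinement: inlier consensus collapsed")
  # axial extent from the largest contiguous run of inlier projections:
  # in-shell outliers beyond the tube ends are separated by visible gaps
  proj <- sort(as.numeric(sweep(pts[inl, , drop = FALSE], 2, ref$point) %*% ref$axis))
  gaps <- diff(proj)
  gap_thr <- max(1, 20 * stats::median(gaps))
  cuts <- c(0L, which(gaps > gap_thr), length(proj))
  runs <- cbind(head(cuts, -1L) + 1L, tail(cuts, -1L))
  main <- runs[which.max(runs[, 2] - runs[, 1]), ]
  len <- proj[main[2]] - proj[main[1]]
  center <- ref$point + (proj[main[1]] + len / 2) * ref$axis
  model <- cylinder_model(center, ref$axis, ref$radius, len)
  structure(list(model = model, inliers = inl,
                 inlier_fraction = mean(inl), iterations = p$max_iterations),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder_fit: radius %.3f mm, length %.2f mm, %.1f%% inliers\n",
              x$model$radius, x$model$length, 100 * x$inlier_fraction))
  invisible(x)
}

#' Deviation of the fitted guiding tube from the planned path
#'
#' @param tube a [cylinder_model()].
#' @param path a [puncture_path()].
#' @return List of class `path_deviation`: `angle` (degrees in `[0, 90]`,
#'   orientation-agnostic), `lateral_offset` (mm, distance from the planned
#'   entry point to the infinite tube axis), `tip_gap` (mm, distance from the
#'   tube end nearer the entry point to the entry point).
#' @export
path_deviation <- function(tube, path) {
  stopifnot(inherits(tube, "cylinder_model"), inherits(path, "puncture_path"))
  cosang <- abs(sum(tube$axis * path$direction))
  angle <- acos(max(-1, min(1, cosang))) * 180 / pi
  rel <- path$entry - tube$center
  along <- sum(rel * tube$axis)
  lateral <- sqrt(max(sum(rel^2) - along^2, 0))
  end1 <- tube$center + (tube$length / 2) * tube$axis
  end2 <- tube$center - (tube$length / 2) * tube$axis
  gap <- min(sqrt(sum((end1 - path$entry)^2)), sqrt(sum((end2 - path$entry)^2)))
  structure(list(angle = angle, lateral_offset = lateral, tip_gap = gap),
            class = "path_deviation")
}

#' @export
print.path_deviation <- function(x, ...) {
  cat(sprintf("path_deviation: angle %.3f deg, lateral offset %.3f mm, tip gap %.3f mm\n",
              x$angle, x$lateral_offset, x$tip_gap))
  invisible(x)
}

#' Gate a path deviation against intraoperative tolerances
#'
#' Pass iff `angle <= max_angle` and `lateral_offset <= max_offset`
#' (boundaries inclusive).
#'
#' @param dev a [path_deviation()].
#' @param max_angle degrees (default 3).
#' @param max_offset mm (default 2).
#' @return List with `pass` (logical) and `message` naming any violated
#'   quantity.
#' @export
check_tolerance <- function(dev, max_angle = 3, max_offset = 2) {
  stopifnot(inherits(dev, "path_deviation"))
  if (max_angle <= 0 || max_offset <= 0) stop("tolerances must be positive")
  bad <- character(0)
  if (dev$angle > max_angle)
    bad <- c(bad, sprintf("angle %.3f deg exceeds %.3f deg", dev$angle, max_angle))
  if (dev$lateral_offset > max_offset)
    bad <- c(bad, sprintf("lateral offset %.3f mm exceeds %.3f mm",
                          dev$lateral_offset, max_offset))
  list(pass = length(bad) == 0L,
       message = if (length(bad) == 0L) "within tolerance" else paste(bad, collapse = "; "))
}

#' Triangulated cylinder for visualization export
#'
#' Builds a closed tube mesh from a fitted cylinder or a planned path (shown
#' as a thin cylinder of the given radius), for export to external viewers.
#'
#' @param x a [cylinder_model()] or [puncture_path()].
#' @param radius radius for a path cylinder (ignored for fitted models), mm.
#' @param n_segments angular resolution.
#' @return A [tri_mesh()].
#' @export
cylinder_mesh <- function(x, radius = 1, n_segments = 32L) {
  if (inherits(x, "puncture_path")) {
    center <- x$entry + (x$depth / 2) * x$direction
    x <- cylinder_model(center, x$direction, radius, x$depth)
  }
  stopifnot(inherits(x, "cylinder_model"))
  B <- .plane_basis(x$axis)
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  ring <- x$radius * (cos(th) %o% B[, 1] + sin(th) %o% B[, 2])
  lo <- sweep(ring, 2, x$center - (x$length / 2) * x$axis, "+")
  hi <- sweep(ring, 2, x$center + (x$length / 2) * x$axis, "+")
  V <- rbind(lo, hi, x$center - (x$length / 2) * x$axis,
             x$center + (x$length / 2) * x$axis)
  m <- n_segments
  i <- seq_len(m); j <- c(2:m, 1L)
  side <- rbind(cbind(i, j, m + i), cbind(j, m + j, m + i))
  cap_lo <- cbind(2L * m + 1L, j, i)
  cap_hi <- cbind(2L * m + 2L, m + i, m + j)
  tri_mesh(V, rbind(side, cap_lo, cap_hi))
}
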