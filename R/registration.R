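## Coarse-to-fine registration of the intraoperative SLI surface cloud to the
## preoperative CT surface model.
##
## Coarse step: least-squares rigid alignment (Kabsch/Umeyama without scale)
## of landmark correspondences taken on conspicuous bandage-fixture features.
## Fine step: trimmed iterative closest point. The ICP moves the (partial)
## SLI cloud onto the CT mesh -- every scan point has a true counterpart on
## the model, whereas the converse does not hold for a one-sided scan. The
## CT->SLI mapping M_SLI = R*M_CT + T is recovered by inversion, which makes
## the total factor exactly as R = R_FM * R_ICP: the fine correction acts in
## CT space, before the coarse feature-match transform.

#' Least-squares rigid alignment of paired landmarks
#'
#' Closed-form Kabsch solution: centroid alignment plus SVD of the
#' cross-covariance with determinant correction, minimizing
#' `sum ||R s_i + T - d_i||^2` over proper rotations.
#'
#' @param src_landmarks n x 3 matrix (n >= 3), source (CT) space, mm.
#' @param dst_landmarks n x 3 matrix, matching points in destination (SLI)
#'   space.
#' @return A [rigid_transform()] mapping source to destination.
#' @export
coarse_align <- function(src_landmarks, dst_landmarks) {
  src <- .as_xyz_matrix(src_landmarks, "src_landmarks")
  dst <- .as_xyz_matrix(dst_landmarks, "dst_landmarks")
  if (nrow(src) != nrow(dst)) stop("landmark lists must have equal length")
  if (nrow(src) < 3L) stop("at least 3 landmark pairs are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2, cs); D <- sweep(dst, 2, cd)
  # collinearity check: second singular value of the centered source
  sv <- svd(S, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate landmarks: configuration is collinear")
  H <- t(S) %*% D
  u <- svd(H)
  sgn <- sign(det(u$v %*% t(u$u)))
  R <- u$v %*% diag(c(1, 1, sgn)) %*% t(u$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' ICP parameter set
#'
#' @param max_iterations iteration cap (default 100).
#' @param rel_tolerance stop when the relative change of the trimmed RMS
#'   falls below this (default 1e-6).
#' @param subsample_size number of source points used for correspondences
#'   (default 5000); the subsample is drawn once per run so the trimmed
#'   objective is fixed and its RMS trace decreases monotonically.
#' @param trim_fraction fraction of largest-distance pairs discarded each
#'   iteration (default 0.2), the standard trimmed-ICP outlier guard.
#' @param max_pair_distance optional hard gate on correspondence distance, mm.
#' @param metric `"auto"` (default: point-to-plane against meshes,
#'   point-to-point against clouds), `"point_to_plane"` or
#'   `"point_to_point"`. The point-to-plane update (Gauss-Newton on the
#'   normal-projected residual) converges in a handful of iterations where
#'   point-to-point creeps tangentially; point-to-point retains the textbook
#'   monotone error trace.
#' @param seed integer seed for the subsample draw.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, rel_tolerance = 1e-6,
                       subsample_size = 5000L, trim_fraction = 0.2,
                       max_pair_distance = NULL,
                       metric = c("auto", "point_to_plane", "point_to_point"),
                       seed = 0L) {
  if (trim_fraction < 0 || trim_fraction >= 1) stop("trim_fraction must be in [0, 1)")
  if (subsample_size < 3L) stop("subsample_size must be at least 3")
  if (max_iterations < 1L) stop("max_iterations must be at least 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance,
                 subsample_size = as.integer(subsample_size),
                 trim_fraction = trim_fraction,
                 max_pair_distance = max_pair_distance,
                 metric = match.arg(metric),
                 seed = as.integer(seed)),
            class = "icp_params")
}

## unit face normals of a mesh
.face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn / pmax(sqrt(rowSums(nn^2)), 1e-300)
}

## one point-to-plane Gauss-Newton step: minimize
## sum over pairs of (n . (p + w x p + t - q))^2 in the small-motion
## linearization, then apply the exact rotation of the solved axis-angle
.plane_step <- function(moved, closest, normals) {
  d <- rowSums((moved - closest) * normals)
  C <- cbind(moved[, 2] * normals[, 3] - moved[, 3] * normals[, 2],
             moved[, 3] * normals[, 1] - moved[, 1] * normals[, 3],
             moved[, 1] * normals[, 2] - moved[, 2] * normals[, 1],
             normals)
  x <- tryCatch(solve(crossprod(C), -crossprod(C, d)),
                error = function(e) rep(0, 6))
  w <- x[1:3]
  th <- sqrt(sum(w^2))
  R <- if (th < 1e-14) diag(3) else {
    u <- w / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  rigid_transform(R, x[4:6])
}

.kabsch_pairs <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  u <- svd(H)
  sgn <- sign(det(u$v %*% t(u$u)))
  R <- u$v %*% diag(c(1, 1, sgn)) %*% t(u$u)
  list(rotation = R, translation = cd - as.numeric(R %*% cs))
}

#' Trimmed iterative-closest-point refinement
#'
#' Iterates: transform the (sub-sampled) source points by the current
#' estimate, find exact nearest points on the target (triangle surface or
#' point cloud) with a KD-tree, discard the `trim_fraction` largest-distance
#' pairs and any pair beyond `max_pair_distance`, and apply the closed-form
#' rigid update; stops when the trimmed RMS change is below `rel_tolerance`
#' or at `max_iterations`.
#'
#' @param src a `point_cloud` (the moving scan).
#' @param dst a `tri_mesh` or `point_cloud` (the fixed model).
#' @param init initial [rigid_transform()] applied to `src` (e.g. the inverse
#'   coarse alignment).
#' @param p an [icp_params()].
#' @return List of class `icp_result`: `total` (init composed with the fine
#'   correction), `fine` (correction relative to `init`), `rms` (final
#'   trimmed RMS, mm), `rms_trace`, `iterations`, `converged`.
#' @export
icp_refine <- function(src, dst, init = rigid_transform(), p = icp_params()) {
  stopifnot(inherits(src, "point_cloud"), inherits(p, "icp_params"))
  n <- n_points(src)
  nsub <- min(p$subsample_size, n)
  if (nsub < 3L) stop("source cloud too small")
  idx <- if (nsub < n) .with_seed(p$seed, sample.int(n, nsub)) else seq_len(n)
  pts0 <- src$points[idx, , drop = FALSE]

  is_mesh <- inherits(dst, "tri_mesh")
  metric <- p$metric
  if (is.null(metric) || metric == "auto")
    metric <- if (is_mesh) "point_to_plane" else "point_to_point"
  if (metric == "point_to_plane" && !is_mesh)
    stop("point_to_plane metric requires a mesh target")
  fnormals <- if (metric == "point_to_plane") .face_normals(dst)

  cur <- init
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  keep_n <- max(3L, floor(nsub * (1 - p$trim_fraction)))
  repeat {
    iter <- iter + 1L
    moved <- apply_transform(pts0, cur)
    cp <- if (is_mesh) {
      res <- cpp_mesh_closest(dst$vertices, dst$faces - 1L, moved)
      list(distance = res$distance, point = res$point, face = res$face)
    } else closest_points(moved, dst)
    ord <- order(cp$distance)
    keep <- ord[seq_len(keep_n)]
    if (!is.null(p$max_pair_distance))
      keep <- keep[cp$distance[keep] <= p$max_pair_distance]
    if (length(keep) < 3L) stop("no usable correspondences: all pairs gated out")
    r <- sqrt(mean(cp$distance[keep]^2))
    trace <- c(trace, r)
    if (r < 1e-9) { converged <- TRUE; break }   # numerically exact alignment
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(prev - r) <= p$rel_tolerance * max(prev, 1e-12)) { converged <- TRUE; break }
    }
    if (iter >= p$max_iterations) break
    upd <- if (metric == "point_to_plane") {
      .plane_step(moved[keep, , drop = FALSE], cp$point[keep, , drop = FALSE],
                  fnormals[cp$face[keep], , drop = FALSE])
    } else {
      k <- .kabsch_pairs(moved[keep, , drop = FALSE], cp$point[keep, , drop = FALSE])
      rigid_transform(k$rotation, k$translation)
    }
    cur <- compose_transforms(cur, upd)
  }
  fine <- compose_transforms(invert_transform(init), cur)
  structure(list(total = cur, fine = fine, rms = trace[length(trace)],
                 rms_trace = trace, iterations = iter, converged = converged,
                 metric = metric),
            class = "icp_result")
}

#' Two-step coarse-to-fine surface registration
#'
#' Runs the landmark coarse alignment (CT -> SLI), refines with trimmed ICP
#' (SLI cloud onto CT mesh), and gates the result with the distance test
#' function: the RMS of the full cropped cloud's nearest distances to the
#' transformed CT model. If the RMS exceeds `quality_threshold` the ICP is
#' restarted with a fresh subsample seed, up to `max_restarts` times, and the
#' best result is returned.
#'
#' @param sli a `point_cloud`: cropped, denoised intraoperative scan
#'   (SLI space).
#' @param ct_surface a `tri_mesh`: preoperative CT surface model (CT space).
#' @param landmarks list with `src` (CT space) and `dst` (SLI space) n x 3
#'   matrices of paired features.
#' @param p an [icp_params()].
#' @param quality_threshold acceptance RMS, mm (default 1.0).
#' @param max_restarts ICP restarts with new subsample seeds (default 3).
#' @param translation `"exact"` or `"additive"` composition of the coarse and
#'   fine translations (see [compose_transforms()]).
#' @return List of class `registration_result`: `coarse`, `fine`, `total`
#'   (all CT -> SLI [rigid_transform()]s, `total` composed fine-then-coarse so
#'   `R = R_FM %*% R_ICP`), `rms` (full-cloud distance RMS, mm), `rms_trace`,
#'   `iterations`, `restarts`, `converged` (`rms <= quality_threshold`).
#' @export
register_two_step <- function(sli, ct_surface, landmarks, p = icp_params(),
                              quality_threshold = 1.0, max_restarts = 3L,
                              translation = c("exact", "additive")) {
  stopifnot(inherits(sli, "point_cloud"), inherits(ct_surface, "tri_mesh"))
  translation <- match.arg(translation)
  coarse <- coarse_align(landmarks$src, landmarks$dst)          # CT -> SLI
  init <- invert_transform(coarse)                              # SLI -> CT
  best <- NULL
  restarts <- -1L
  for (attempt in 0:max_restarts) {
    pa <- p
    pa$seed <- p$seed + attempt
    icp <- icp_refine(sli, ct_surface, init = init, p = pa)
    # full-cloud distance test against the CT model in CT space
    moved_full <- apply_transform(sli, icp$total)
    full_rms <- rms(nearest_distances(moved_full, ct_surface))
    if (is.null(best) || full_rms < best$rms) {
      fine <- invert_transform(icp$fine)                        # CT-space correction
      total <- compose_transforms(fine, coarse, translation = translation)
      best <- structure(list(coarse = coarse, fine = fine, total = total,
                             rms = full_rms, rms_trace = icp$rms_trace,
                             iterations = icp$iterations,
                             restarts = attempt,
                             seed = pa$seed,
                             converged = full_rms <= quality_threshold),
                        class = "registration_result")
    }
    restarts <- attempt
    if (best$converged) break
  }
  best
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: rms %.4f mm, %d ICP iterations, %s\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "NOT within threshold"))
  invisible(x)
}

#' Crop and denoise a scan cloud
#'
#' Keeps points inside an axis-aligned box, then applies statistical outlier
#' removal: a point is kept when its mean distance to its `nn_k` nearest
#' neighbours is within `mean + sigma_factor * SD` of that statistic over the
#' boxed cloud.
#'
#' @param cloud a `point_cloud`.
#' @param box optional 2 x 3 matrix `rbind(min_xyz, max_xyz)` in mm; `NULL`
#'   keeps everything.
#' @param nn_k neighbour count for the outlier statistic (default 8).
#' @param sigma_factor gate width in standard deviations (default 2).
#' @return The filtered `point_cloud`.
#' @export
crop_and_denoise <- function(cloud, box = NULL, nn_k = 8L, sigma_factor = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  keep <- rep(TRUE, nrow(pts))
  if (!is.null(box)) {
    box <- as.matrix(box)
    stopifnot(nrow(box) == 2L, ncol(box) == 3L)
    keep <- pts[, 1] >= box[1, 1] & pts[, 1] <= box[2, 1] &
            pts[, 2] >= box[1, 2] & pts[, 2] <= box[2, 2] &
            pts[, 3] >= box[1, 3] & pts[, 3] <= box[2, 3]
    if (!any(keep)) stop("crop box excludes every point")
  }
  sub <- pts[keep, , drop = FALSE]
  if (nrow(sub) > nn_k) {
    kn <- cpp_knn(sub, sub, as.integer(nn_k + 1L))
    mean_d <- rowMeans(kn$distance[, -1L, drop = FALSE])
    gate <- mean(mean_d) + sigma_factor * sd(mean_d)
    inliers <- mean_d <= gate
  } else inliers <- rep(TRUE, nrow(sub))
  sel <- which(keep)[inliers]
  point_cloud(pts[sel, , drop = FALSE],
              normals = if (!is.null(cloud$normals)) cloud$normals[sel, , drop = FALSE],
              scalars = if (!is.null(cloud$scalars)) cloud$scalars[sel])
}
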