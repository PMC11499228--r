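## Nearest-distance queries: the "distance test function" used to gate the
## registration quality and to quantify surface/skeletal drift. Point-to-mesh
## queries return the exact distance to the closest point on any triangle;
## point-to-cloud queries return the exact nearest-neighbour distance. Both
## are KD-tree accelerated but exact (no approximate search): drift is
## quantified at the few-hundredths-of-a-millimetre scale.

.query_matrix <- function(query) {
  if (inherits(query, "point_cloud")) query$points
  else if (inherits(query, "tri_mesh")) query$vertices
  else .as_xyz_matrix(query)
}

#' Per-point nearest distances from a query set to a target
#'
#' For a `tri_mesh` target, the distance from each query point to the closest
#' point on any triangle (exact point-to-surface distance); for a
#' `point_cloud` target, the Euclidean distance to the nearest target point.
#'
#' @param query a `point_cloud`, `tri_mesh` (its vertices are used) or matrix.
#' @param target a `point_cloud` or `tri_mesh`.
#' @return Numeric vector of distances (mm), one per query point.
#' @export
nearest_distances <- function(query, target) {
  q <- .query_matrix(query)
  if (nrow(q) == 0L) stop("empty query")
  if (inherits(target, "tri_mesh")) {
    cpp_mesh_closest(target$vertices, target$faces - 1L, q)$distance
  } else if (inherits(target, "point_cloud")) {
    if (n_points(target) == 0L) stop("empty target")
    as.numeric(cpp_knn(target$points, q, 1L)$distance)
  } else {
    tm <- .as_xyz_matrix(target, "target")
    if (nrow(tm) == 0L) stop("empty target")
    as.numeric(cpp_knn(tm, q, 1L)$distance)
  }
}

#' Closest points on a target for a query set
#'
#' Like [nearest_distances()] but also returns the closest point coordinates,
#' as needed for ICP correspondences.
#'
#' @param query a `point_cloud` or matrix of query points.
#' @param target a `point_cloud` or `tri_mesh`.
#' @return List with `distance` (numeric) and `point` (n x 3 matrix).
#' @export
closest_points <- function(query, target) {
  q <- .query_matrix(query)
  if (nrow(q) == 0L) stop("empty query")
  if (inherits(target, "tri_mesh")) {
    res <- cpp_mesh_closest(target$vertices, target$faces - 1L, q)
    list(distance = res$distance, point = res$point)
  } else {
    tm <- if (inherits(target, "point_cloud")) target$points else .as_xyz_matrix(target, "target")
    if (nrow(tm) == 0L) stop("empty target")
    res <- cpp_knn(tm, q, 1L)
    list(distance = as.numeric(res$distance), point = tm[as.integer(res$index), , drop = FALSE])
  }
}

#' k-nearest-neighbour query between point sets
#'
#' @param target n x 3 matrix or `point_cloud` searched in.
#' @param query m x 3 matrix or `point_cloud` of query points.
#' @param k number of neighbours.
#' @return List with `index` (m x k, 1-based into target) and `distance` (m x k).
#' @export
knn_points <- function(target, query, k = 1L) {
  tm <- if (inherits(target, "point_cloud")) target$points else .as_xyz_matrix(target, "target")
  qm <- if (inherits(query, "point_cloud")) query$points else .as_xyz_matrix(query, "query")
  cpp_knn(tm, qm, as.integer(k))
}

#' Root-mean-square of a distance vector
#' @param d numeric vector of distances, mm.
#' @return `sqrt(mean(d^2))`.
#' @export
rms <- function(d) sqrt(mean(d^2))
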