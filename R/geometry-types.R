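## Core geometric containers. Everything is plain base-R S3: a point cloud is
## a list holding an n x 3 matrix of mm coordinates, a mesh holds vertices and
## 1-based faces, a rigid transform a 3x3 rotation and a 3-vector translation.

.as_xyz_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(x, nrow = 1L)
    else stop(sprintf("%s must be an n x 3 matrix", what))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite coordinates", what))
  dimnames(x) <- NULL
  x
}

#' Construct a point cloud
#'
#' An unordered set of 3D points in mm, optionally with unit normals and a
#' per-point scalar channel (used e.g. for distances in heat-map exports).
#'
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @param normals optional n x 3 matrix of unit normals.
#' @param scalars optional numeric vector of length n.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, scalars = NULL) {
  points <- .as_xyz_matrix(points)
  if (nrow(points) == 0L) stop("point cloud must contain at least one point")
  if (!is.null(normals)) {
    normals <- .as_xyz_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop("normals count must equal point count")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("normals must be unit length (tolerance 1e-6)")
  }
  if (!is.null(scalars)) {
    scalars <- as.numeric(scalars)
    if (length(scalars) != nrow(points))
      stop("scalars count must equal point count")
  }
  structure(list(points = points, normals = normals, scalars = scalars),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s%s\n", nrow(x$points),
              if (!is.null(x$normals)) ", with normals" else "",
              if (!is.null(x$scalars)) ", with scalars" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param x a `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(x) nrow(x$points)

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- .as_xyz_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stop("mesh must be non-empty")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]))
    stop("faces must not repeat a vertex index")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Construct a rigid transform
#'
#' A proper rigid body motion `p -> rotation %*% p + translation` mapping one
#' mm coordinate frame into another (e.g. CT space into the intraoperative
#' structured-light camera space).
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 numeric vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("transform contains non-finite values")
  err <- norm(crossprod(rotation) - diag(3), "F")
  if (err > 1e-8)
    stop(sprintf("rotation is not orthonormal (deviation %.3g)", err))
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Construct a CT-like scalar volume
#'
#' @param values 3D numeric array of Hounsfield units.
#' @param spacing length-3 positive vector, mm per voxel.
#' @param origin length-3 vector, mm: world coordinate of the center of voxel
#'   index (1,1,1) (voxel-center convention, world = origin + (index-1)*spacing).
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3L) stop("origin must have length 3")
  if (prod(dim(values)) == 0L) stop("volume grid must be non-empty")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("hu_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a binary mask congruent with a volume grid
#'
#' @param values 3D logical array.
#' @param spacing,origin grid geometry inherited from the source volume.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  storage.mode(values) <- "logical"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("binary_mask: %d x %d x %d voxels, %d true\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Construct a fitted cylinder model
#'
#' Represents the puncture guiding tube as recovered from its surface scan:
#' an axis segment of given length centered at `center`, with radius `radius`.
#'
#' @param center length-3 vector, mm: midpoint of the axis segment.
#' @param axis length-3 unit vector.
#' @param radius positive, mm.
#' @param length positive, mm.
#' @return An object of class `cylinder_model`.
#' @export
cylinder_model <- function(center, axis, radius, length) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  if (length(center) != 3L || length(axis) != 3L) stop("center and axis must be 3-vectors")
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("axis must be unit length")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (!is.numeric(length) || length <= 0) stop("length must be positive")
  structure(list(center = center, axis = axis, radius = as.numeric(radius),
                 length = as.numeric(length)),
            class = "cylinder_model")
}

#' @export
print.cylinder_model <- function(x, ...) {
  cat(sprintf("cylinder_model: radius %.3f mm, length %.3f mm, axis (%.3f, %.3f, %.3f)\n",
              x$radius, x$length, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Construct a planned puncture path
#'
#' @param entry length-3 vector, mm: skin entry point in CT coordinates.
#' @param direction length-3 unit vector from entry toward the target.
#' @param depth positive, mm.
#' @return An object of class `puncture_path`.
#' @export
puncture_path <- function(entry, direction, depth) {
  entry <- as.numeric(entry); direction <- as.numeric(direction)
  if (length(entry) != 3L || length(direction) != 3L) stop("entry and direction must be 3-vectors")
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-8) stop("direction must be unit length")
  if (!is.numeric(depth) || depth <= 0) stop("depth must be positive")
  structure(list(entry = entry, direction = direction, depth = as.numeric(depth)),
            class = "puncture_path")
}

#' @export
print.puncture_path <- function(x, ...) {
  cat(sprintf("puncture_path: entry (%.2f, %.2f, %.2f) mm, depth %.2f mm\n",
              x$entry[1], x$entry[2], x$entry[3], x$depth))
  invisible(x)
}

.unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize a zero vector")
  v / n
}

## world coordinates of all voxel centers of a grid (used by tests/fixtures)
.voxel_centers <- function(dims, spacing, origin) {
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}
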