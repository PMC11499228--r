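## Rigid-transform algebra. The registration pipeline represents the mapping
## from CT (preoperative, virtual) space into SLI (intraoperative, real) space
## as M_SLI = R * M_CT + T, with R and T assembled from a coarse feature-match
## step (R_FM, T_FM) and a fine ICP step (R_ICP, T_ICP) as R = R_FM * R_ICP.

#' Apply a rigid transform to points, a cloud or a mesh
#'
#' Maps every point `p` to `rotation %*% p + translation`. For point clouds
#' normals are rotated (not translated); scalars are carried over unchanged.
#'
#' @param model a `point_cloud`, `tri_mesh`, or n x 3 matrix.
#' @param t a `rigid_transform`.
#' @return An object of the same kind as `model`.
#' @export
apply_transform <- function(model, t) {
  stopifnot(inherits(t, "rigid_transform"))
  UseMethod("apply_transform")
}

#' @export
apply_transform.default <- function(model, t) {
  pts <- .as_xyz_matrix(model)
  sweep(pts %*% t(t$rotation), 2, t$translation, "+")
}

#' @export
apply_transform.point_cloud <- function(model, t) {
  out <- model
  out$points <- apply_transform.default(model$points, t)
  if (!is.null(model$normals)) out$normals <- model$normals %*% t(t$rotation)
  out
}

#' @export
apply_transform.tri_mesh <- function(model, t) {
  out <- model
  out$vertices <- apply_transform.default(model$vertices, t)
  out
}

#' Compose two rigid transforms
#'
#' Returns the transform `g` with `g(p) = second(first(p))`: rotation
#' `R_second %*% R_first`, translation `R_second %*% T_first + T_second`.
#'
#' The two-step registration literature sometimes writes the combined
#' translation additively as `T = T_first + T_second`; that shortcut is exact
#' only when the second rotation is the identity (a fine step that is a pure
#' translation). It is available as `translation = "additive"` for
#' reproducing that convention, but the exact composition is the default.
#'
#' @param first,second `rigid_transform` objects, applied in that order.
#' @param translation `"exact"` (default) or `"additive"` (legacy shortcut).
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(first, second, translation = c("exact", "additive")) {
  stopifnot(inherits(first, "rigid_transform"), inherits(second, "rigid_transform"))
  translation <- match.arg(translation)
  rot <- second$rotation %*% first$rotation
  tr <- if (translation == "exact")
    as.numeric(second$rotation %*% first$translation) + second$translation
  else
    first$translation + second$translation
  rigid_transform(rot, tr)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return The `rigid_transform` `t^-1` with `compose_transforms(t, t^-1)`
#'   equal to the identity.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rot <- t(t$rotation)
  rigid_transform(rot, -as.numeric(rot %*% t$translation))
}

#' Elementary rotation about a coordinate axis
#'
#' Convenience constructor used throughout the phantom studies.
#'
#' @param axis `"x"`, `"y"` or `"z"`, or a length-3 vector.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @param translation optional length-3 mm translation.
#' @return A `rigid_transform`.
#' @export
rotation_transform <- function(axis = "z", angle_deg = 0, translation = c(0, 0, 0)) {
  u <- if (is.character(axis)) {
    switch(match.arg(axis, c("x", "y", "z")),
           x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  } else .unitize(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}

#' Pure translation transform
#' @param translation length-3 mm vector.
#' @return A `rigid_transform`.
#' @export
translation_transform <- function(translation) {
  rigid_transform(diag(3), translation)
}
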