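## Preoperative navigation-map construction: Hounsfield threshold
## segmentation, connected-component cleanup, isosurface extraction and
## puncture-path planning. The clinical presets follow the navigation
## workstation protocol: body surface -650 HU to maximum, skeleton 125 HU to
## maximum.

#' Hounsfield-unit threshold segmentation
#'
#' @param v an [hu_volume()].
#' @param low lower HU bound (inclusive).
#' @param high upper HU bound (inclusive); `Inf` means "maximum".
#' @return A [binary_mask()] true where `low <= HU <= high`.
#' @export
threshold_mask <- function(v, low, high = Inf) {
  stopifnot(inherits(v, "hu_volume"))
  if (low >= high) stop("low threshold must be below high threshold")
  binary_mask(v$values >= low & v$values <= high, v$spacing, v$origin)
}

#' HU presets for the navigation map
#'
#' `"surface"` selects everything from -650 HU up (soft tissue and bone,
#' excluding air); `"skeleton"` selects 125 HU and up (bone).
#'
#' @param v an [hu_volume()].
#' @param preset `"surface"` or `"skeleton"`.
#' @return A [binary_mask()].
#' @export
threshold_preset <- function(v, preset = c("surface", "skeleton")) {
  preset <- match.arg(preset)
  threshold_mask(v, low = if (preset == "surface") -650 else 125, high = Inf)
}

#' Keep the largest connected component of a mask
#'
#' Deterministic stand-in for the interactive region-growing/mask-editing
#' step: small disconnected islands (noise, table parts) are discarded.
#'
#' @param m a [binary_mask()].
#' @param connectivity 6 (face) or 26 (face+edge+corner neighbours).
#' @return A [binary_mask()] true only on the largest component.
#' @export
largest_component <- function(m, connectivity = 26) {
  stopifnot(inherits(m, "binary_mask"))
  if (!any(m$values)) stop("mask is empty")
  lab <- cpp_label_components(as.logical(m$values), dim(m$values), as.integer(connectivity))
  keep <- which.max(lab$sizes)
  binary_mask(array(lab$label == keep, dim(m$values)), m$spacing, m$origin)
}

#' Label connected components of a mask
#'
#' @param m a [binary_mask()].
#' @param connectivity 6 or 26.
#' @return List with `label` (integer array, 0 = background) and `sizes`.
#' @export
label_components <- function(m, connectivity = 26) {
  stopifnot(inherits(m, "binary_mask"))
  cpp_label_components(as.logical(m$values), dim(m$values), as.integer(connectivity))
}

#' Morphological closing of a mask (box kernel)
#'
#' Optional cleanup after thresholding; radius in voxels.
#'
#' @param m a [binary_mask()].
#' @param radius integer voxel radius (0 = no-op).
#' @return A [binary_mask()].
#' @export
close_mask <- function(m, radius = 1L) {
  stopifnot(inherits(m, "binary_mask"))
  radius <- as.integer(radius)
  if (radius <= 0L) return(m)
  dilate1 <- function(a) {
    d <- dim(a); out <- a
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      n <- d[ax]
      if (s > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1L) }
      else { idx_dst[[ax]] <- 1:(n - 1L); idx_src[[ax]] <- 2:n }
      shifted <- do.call(`[<-`, c(list(shifted), idx_dst,
                                  list(do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
      out <- out | shifted
    }
    out
  }
  a <- m$values
  for (i in seq_len(radius)) a <- dilate1(a)
  for (i in seq_len(radius)) a <- !dilate1(!a)
  binary_mask(a, m$spacing, m$origin)
}

#' Extract a triangulated isosurface from a binary mask
#'
#' Dual-contouring (surface-net) isosurface at the 0.5 level of the binary
#' grid: one vertex per mixed-occupancy dual cell at the mean of its
#' edge-crossing midpoints, one quad (two triangles) per sign-change voxel
#' edge. The mask is padded with a false border so surfaces touching the grid
#' boundary close. Vertices are in world mm (voxel-center convention).
#'
#' @param m a [binary_mask()].
#' @return A [tri_mesh()] with outward-oriented faces.
#' @export
extract_surface <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  a <- m$values
  if (!any(a)) stop("mask has no true voxel")
  if (all(a)) stop("mask has no false voxel")
  d <- dim(a)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  res <- cpp_surface_nets(as.logical(padded), dim(padded), m$spacing,
                          m$origin - m$spacing)
  tri_mesh(res$vertices, res$faces + 1L)
}

#' Surface area of a mesh (mm^2)
#' @param mesh a `tri_mesh`.
#' @return Total triangle area.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3, divergence theorem)
#' @param mesh a closed, outward-oriented `tri_mesh`.
#' @return Signed enclosed volume (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]; c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Plan a straight puncture path
#'
#' @param entry length-3 mm vector: skin entry point (CT space).
#' @param target length-3 mm vector: anatomical target.
#' @return A [puncture_path()] with `direction = (target - entry)/depth`,
#'   `depth = ||target - entry||`.
#' @export
plan_path <- function(entry, target) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  d <- target - entry
  depth <- sqrt(sum(d^2))
  if (depth < 1e-12) stop("entry and target coincide")
  puncture_path(entry, d / depth, depth)
}

#' Polymer bandage strapping length
#'
#' Approximate length (cm) of polymer bandage needed to strap a limb of
#' diameter `d` cm during surface fixation: `L = 2*d + 10`.
#'
#' @param d limb diameter at the strapping site, cm.
#' @return Bandage length, cm.
#' @export
bandage_length <- function(d) {
  if (!is.numeric(d) || any(d <= 0)) stop("diameter must be positive")
  2 * d + 10
}

#' Segment a volume with a clinical preset and extract the model surface
#'
#' Convenience wrapper: threshold preset, largest connected component,
#' optional closing, isosurface.
#'
#' @param v an [hu_volume()].
#' @param preset `"surface"` or `"skeleton"`.
#' @param connectivity component connectivity (default 26).
#' @param closing_radius voxel radius for morphological closing (default 0).
#' @return A [tri_mesh()].
#' @export
segment_model <- function(v, preset = c("surface", "skeleton"),
                          connectivity = 26, closing_radius = 0L) {
  m <- threshold_preset(v, preset)
  m <- largest_component(m, connectivity)
  if (closing_radius > 0L) m <- close_mask(m, closing_radius)
  extract_surface(m)
}
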