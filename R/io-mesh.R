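## Mesh and point-cloud file I/O: PLY (ascii + binary little endian) for
## clouds and meshes, STL (binary + ascii) for meshes, whitespace XYZ for
## clouds. Per-vertex scalars travel in the PLY "quality" property, colors in
## uchar red/green/blue, matching what MeshLab/CloudCompare expect.

#' Write a point cloud or mesh to PLY
#'
#' @param x a `point_cloud` or `tri_mesh`.
#' @param path output file path.
#' @param format `"binary"` (binary_little_endian 1.0) or `"ascii"`.
#' @param colors optional n x 3 integer matrix (0-255 RGB per vertex).
#' @param scalars optional numeric vector written as the per-vertex float
#'   property `quality`; defaults to the cloud's own scalar channel.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path, format = c("binary", "ascii"),
                      colors = NULL, scalars = NULL) {
  format <- match.arg(format)
  is_mesh <- inherits(x, "tri_mesh")
  pts <- if (is_mesh) x$vertices else x$points
  normals <- if (!is_mesh) x$normals else NULL
  if (is.null(scalars) && !is_mesh) scalars <- x$scalars
  n <- nrow(pts)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == n, ncol(colors) == 3)
    storage.mode(colors) <- "integer"
  }
  if (!is.null(scalars)) stopifnot(length(scalars) == n)

  hdr <- c("ply",
           if (format == "binary") "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment punctnav",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (!is.null(normals)) hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (!is.null(colors)) hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  if (!is.null(scalars)) hdr <- c(hdr, "property float quality")
  if (is_mesh) hdr <- c(hdr, sprintf("element face %d", nrow(x$faces)),
                        "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vert_num <- pts
  if (!is.null(normals)) vert_num <- cbind(vert_num, normals)
  ns <- ncol(vert_num)
  if (format == "ascii") {
    cols <- as.list(as.data.frame(vert_num))
    if (!is.null(colors)) cols <- c(cols, as.list(as.data.frame(colors)))
    if (!is.null(scalars)) cols <- c(cols, list(scalars))
    lines <- do.call(paste, cols)
    writeLines(lines, con, sep = "\n")
    if (is_mesh) {
      f0 <- x$faces - 1L
      writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con, sep = "\n")
    }
  } else {
    ncol_f <- ns + (if (is.null(scalars)) 0L else 1L)
    fl <- matrix(0, n, ncol_f)
    fl[, seq_len(ns)] <- vert_num
    if (!is.null(scalars)) fl[, ncol_f] <- scalars
    bytes_per <- 4L * ncol_f + (if (is.null(colors)) 0L else 3L)
    fl_raw <- writeBin(as.numeric(t(fl)), raw(), size = 4L, endian = "little")
    if (is.null(colors)) {
      raw_all <- fl_raw
    } else {
      # interleave float block and color block per record: colors sit after
      # the coordinate/normal floats and before quality
      col_raw <- as.raw(t(colors))
      pos_cols <- 4L * ns
      raw_all <- raw(n * bytes_per)
      idx_rec <- (seq_len(n) - 1L) * bytes_per
      for (b in seq_len(pos_cols))
        raw_all[idx_rec + b] <- fl_raw[(seq_len(n) - 1L) * (4L * ncol_f) + b]
      for (b in 1:3)
        raw_all[idx_rec + pos_cols + b] <- col_raw[(seq_len(n) - 1L) * 3L + b]
      if (!is.null(scalars))
        for (b in 1:4)
          raw_all[idx_rec + pos_cols + 3L + b] <-
            fl_raw[(seq_len(n) - 1L) * (4L * ncol_f) + pos_cols + b]
    }
    writeBin(raw_all, con)
    if (is_mesh) {
      f0 <- t(x$faces - 1L)
      cnt_raw <- as.raw(3L)
      frec <- raw(nrow(x$faces) * 13L)
      idx_rec <- (seq_len(nrow(x$faces)) - 1L) * 13L
      frec[idx_rec + 1L] <- cnt_raw
      ib <- writeBin(as.integer(f0), raw(), size = 4L, endian = "little")
      for (b in seq_len(12L))
        frec[idx_rec + 1L + b] <- ib[(seq_len(nrow(x$faces)) - 1L) * 12L + b]
      writeBin(frec, con)
    }
  }
  invisible(path)
}

.parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file")
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[5], list = TRUE,
                                                    count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  list(format = fmt, elements = elements)
}

.ply_type_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop(sprintf("unsupported PLY type '%s'", type)))
}

.ply_read_scalar <- function(con, type) {
  sz <- .ply_type_size(type)
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "numeric", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

#' Read a PLY file as a point cloud or mesh
#'
#' Supports ascii and binary_little_endian files with float/uchar vertex
#' properties; a `quality` property is read into the scalar channel, `nx/ny/nz`
#' into normals.
#'
#' @param path PLY file path.
#' @return A `tri_mesh` if the file has faces, otherwise a `point_cloud`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .parse_ply_header(con)
  ve <- hdr$elements[["vertex"]]
  if (is.null(ve)) stop("PLY file has no vertex element")
  pnames <- vapply(ve$props, function(p) p$name, "")
  if (identical(hdr$format, "ascii")) {
    # read remaining lines as tokens
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vlines <- rest[seq_len(ve$count)]
    vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    colnames(vm) <- pnames[seq_len(ncol(vm))]
    fe <- hdr$elements[["face"]]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0) {
      flines <- rest[ve$count + seq_len(fe$count)]
      fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), as.numeric))
      if (any(fm[, 1] != 3)) stop("only triangular PLY faces are supported")
      faces <- matrix(as.integer(fm[, 2:4] + 1L), ncol = 3L)
    }
  } else if (identical(hdr$format, "binary_little_endian")) {
    sizes <- vapply(ve$props, function(p) .ply_type_size(p$type), 0L)
    types <- vapply(ve$props, function(p) p$type, "")
    rec <- sum(sizes)
    blob <- readBin(con, "raw", ve$count * rec)
    vm <- matrix(NA_real_, ve$count, length(pnames))
    offset <- 0L
    for (j in seq_along(pnames)) {
      pos <- as.vector(outer(seq_len(sizes[j]), (seq_len(ve$count) - 1L) * rec + offset, "+"))
      col_raw <- blob[pos]
      vm[, j] <- if (types[j] %in% c("float", "float32", "double", "float64"))
        readBin(col_raw, "numeric", ve$count, size = sizes[j], endian = "little")
      else
        as.numeric(readBin(col_raw, "integer", ve$count, size = sizes[j], endian = "little",
                           signed = !(types[j] %in% c("uchar", "uint8", "ushort", "uint16"))))
      offset <- offset + sizes[j]
    }
    colnames(vm) <- pnames
    fe <- hdr$elements[["face"]]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0) {
      lp <- fe$props[[1]]
      csz <- .ply_type_size(lp$count_type); isz <- .ply_type_size(lp$type)
      frec <- csz + 3L * isz
      fblob <- readBin(con, "raw", fe$count * frec)
      cnts <- as.integer(fblob[(seq_len(fe$count) - 1L) * frec + 1L])
      if (any(cnts != 3L)) stop("only triangular PLY faces are supported")
      ipos <- as.vector(outer(seq_len(3L * isz), (seq_len(fe$count) - 1L) * frec + csz, "+"))
      idx <- readBin(fblob[ipos], "integer", 3L * fe$count, size = isz, endian = "little")
      faces <- matrix(idx, ncol = 3L, byrow = TRUE) + 1L
    }
  } else stop(sprintf("unsupported PLY format '%s'", hdr$format))

  get_cols <- function(nm) if (all(nm %in% colnames(vm))) vm[, nm, drop = FALSE] else NULL
  pts <- get_cols(c("x", "y", "z"))
  if (is.null(pts)) stop("PLY vertex element lacks x/y/z")
  if (!is.null(faces)) return(tri_mesh(pts, faces))
  normals <- get_cols(c("nx", "ny", "nz"))
  if (!is.null(normals)) {
    nn <- sqrt(rowSums(normals^2))
    normals <- normals / pmax(nn, 1e-12)
  }
  scal <- if ("quality" %in% colnames(vm)) vm[, "quality"] else NULL
  point_cloud(pts, normals = normals, scalars = scal)
}

#' Write a mesh to STL
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]; c_ <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ln <- sqrt(rowSums(nrm^2)); nrm <- nrm / pmax(ln, 1e-300)
  nf <- nrow(F)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid punctnav", con)
    tpl <- paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                  "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                  " endloop\nendfacet")
    writeLines(sprintf(tpl, nrm[, 1], nrm[, 2], nrm[, 3],
                       a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                       c_[, 1], c_[, 2], c_[, 3]), con)
    writeLines("endsolid punctnav", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", "punctnav binary STL")), as.raw(0)), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    dat <- t(cbind(nrm, a, b, c_))                       # 12 floats per facet
    fl <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
    rec <- raw(nf * 50L)
    idx <- (seq_len(nf) - 1L) * 50L
    for (bb in seq_len(48L)) rec[idx + bb] <- fl[(seq_len(nf) - 1L) * 48L + bb]
    writeBin(rec, con)
  }
  invisible(path)
}

#' Read an STL file (binary or ascii)
#'
#' Duplicate vertices shared by adjacent facets are merged exactly.
#'
#' @param path STL file path.
#' @return A `tri_mesh`.
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", 512L)
  is_ascii <- identical(rawToChar(head5[1:5]), "solid") &&
    !any(head5 == as.raw(0))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    vm <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t) as.numeric(t[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    blob <- readBin(con, "raw", nf * 50L)
    idx <- (seq_len(nf) - 1L) * 50L
    fpos <- as.vector(outer(seq_len(48L), idx, "+"))
    fl <- readBin(blob[fpos], "numeric", 12L * nf, size = 4L, endian = "little")
    fm <- matrix(fl, ncol = 12L, byrow = TRUE)
    # interleaved (v1, v2, v3) per facet
    vm <- matrix(t(fm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  }
  key <- paste(vm[, 1], vm[, 2], vm[, 3])
  uk <- !duplicated(key)
  verts <- vm[uk, , drop = FALSE]
  map <- match(key, key[uk])
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Read a whitespace-delimited XYZ point file
#'
#' @param path text file with `x y z` (optionally `nx ny nz`) per line.
#' @return A `point_cloud`.
#' @export
read_xyz <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) >= 6) {
    nn <- m[, 4:6, drop = FALSE]
    nn <- nn / pmax(sqrt(rowSums(nn^2)), 1e-12)
    point_cloud(m[, 1:3, drop = FALSE], normals = nn)
  } else point_cloud(m[, 1:3, drop = FALSE])
}

#' Write a point cloud to a whitespace XYZ file
#' @param cloud a `point_cloud`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  m <- cloud$points
  if (!is.null(cloud$normals)) m <- cbind(m, cloud$normals)
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read landmark correspondences
#'
#' Plain-text file with one correspondence per line: six numbers, the CT-space
#' point then the matching SLI-space point (mm).
#'
#' @param path text file path.
#' @return List with `src` and `dst` n x 3 matrices (CT then SLI).
#' @export
read_landmarks <- function(path) {
  m <- unname(as.matrix(read.table(path)))
  if (ncol(m) != 6L) stop("landmark file must have 6 columns per line")
  list(src = m[, 1:3, drop = FALSE], dst = m[, 4:6, drop = FALSE])
}

#' Write landmark correspondences
#' @param src,dst n x 3 matrices (CT-space, SLI-space).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(src, dst, path) {
  write.table(cbind(src, dst), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
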