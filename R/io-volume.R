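## CT volume I/O. NIfTI goes through RNifti; NRRD is handled by a minimal
## reader/writer for attached raw/gzip data (the subset CT workstations emit).
## Spacing is carried in pixdim / "spacings", the world origin in the sform /
## "space origin" (voxel-center convention).

#' Read a CT volume (NIfTI or NRRD)
#'
#' @param path file ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return An [hu_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(.read_nrrd(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  attributes(arr) <- list(dim = dim(arr))
  sp <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && !isTRUE(attr(xf, "code") == 0)) {
    origin <- as.numeric(xf[1:3, 4])
    sp_x <- sqrt(colSums(xf[1:3, 1:3]^2))
    if (all(sp_x > 0)) sp <- sp_x
  }
  hu_volume(arr, spacing = sp, origin = origin)
}

#' Write a CT volume (NIfTI or NRRD)
#'
#' @param v an [hu_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "hu_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(.write_nrrd(v, path))
  aff <- diag(4)
  aff[1, 1] <- v$spacing[1]; aff[2, 2] <- v$spacing[2]; aff[3, 3] <- v$spacing[3]
  aff[1:3, 4] <- v$origin
  img <- RNifti::asNifti(v$values, pixdim = v$spacing)
  RNifti::sform(img) <- structure(aff, code = 2L)   # spacing rides in the sform
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header not terminated by blank line")
    if (!nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirm <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]])))
    spacing <- sqrt(rowSums(dirm^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  nvox <- prod(dims)
  rest <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) rest <- memDecompress(rest, type = "gzip")
  else if (enc != "raw") stop(sprintf("unsupported NRRD encoding '%s'", enc))
  vals <- switch(type,
    "float" = readBin(rest, "numeric", nvox, size = 4L, endian = "little"),
    "double" = readBin(rest, "numeric", nvox, size = 8L, endian = "little"),
    "short" = , "int16" = readBin(rest, "integer", nvox, size = 2L, endian = "little"),
    "int" = , "int32" = readBin(rest, "integer", nvox, size = 4L, endian = "little"),
    stop(sprintf("unsupported NRRD type '%s'", type)))
  hu_volume(array(as.numeric(vals), dims), spacing = spacing, origin = origin)
}

.write_nrrd <- function(v, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(v$values)
  hdr <- c("NRRD0004",
           "# punctnav CT volume",
           "type: float",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   v$spacing[1], v$spacing[2], v$spacing[3]),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: gzip",
           sprintf("space origin: (%g,%g,%g)", v$origin[1], v$origin[2], v$origin[3]),
           "")
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.numeric(v$values), raw(), size = 4L, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}
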