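#' Binary voxel volumes
#'
#' CT-like container for colony occupancy: a 3D logical array plus a
#' per-axis voxel pitch (anisotropic spacing is common in CT, e.g.
#' 0.35 x 0.35 x 0.30 mm) and a physical origin (position of the corner of
#' voxel `[1,1,1]`).
#'
#' @param mask logical (or 0/1) 3D array.
#' @param pitch numeric length-3 voxel spacing (m).
#' @param origin numeric length-3 corner position (m).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(mask, pitch, origin = c(0, 0, 0)) {
  stopifnot(length(dim(mask)) == 3, length(pitch) == 3, all(pitch > 0))
  mask <- array(as.logical(mask), dim = dim(mask))
  structure(list(mask = mask, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, pitch %s mm, %d foreground\n",
              paste(dim(x$mask), collapse = "x"),
              paste(signif(x$pitch * 1e3, 3), collapse = "/"),
              sum(x$mask)))
  invisible(x)
}

#' Keep only the largest connected component
#'
#' @param volume a [voxel_volume()].
#' @param connectivity 26 (default) or 6.
#' @return the filtered volume.
#' @export
largest_component <- function(volume, connectivity = 26L) {
  lab <- cpp_label_components(volume$mask, dim(volume$mask),
                              as.integer(connectivity))
  volume$mask <- array(lab == 1L, dim = dim(volume$mask))
  volume
}

# voxel centre coordinates for index triples (rows of idx, 1-based)
voxel_centers <- function(volume, idx) {
  sweep(sweep(idx - 0.5, 2, volume$pitch, "*"), 2, volume$origin, "+")
}

#' Voxelize a triangulated surface into a standalone volume
#'
#' Rasterizes the closed colony surface onto a fresh voxel grid covering its
#' bounding box (plus padding), independent of any flow domain; used to feed
#' the morphometric pipeline at CT-like resolution.
#'
#' @param surface a [tri_surface()].
#' @param pitch voxel spacing (m), scalar or length-3.
#' @param pad number of empty voxels added around the bounding box.
#' @return a [voxel_volume()].
#' @export
mesh_to_volume <- function(surface, pitch, pad = 2L) {
  if (length(pitch) == 1) pitch <- rep(pitch, 3)
  cs <- closed_surface_faces(surface)
  lo <- apply(cs$v, 2, min) - pad * pitch
  hi <- apply(cs$v, 2, max) + pad * pitch
  n <- pmax(ceiling((hi - lo) / pitch), 1L)
  mask <- cpp_voxelize_mesh(cs$v, cs$f, as.integer(n), pitch, lo)
  if (isTRUE(attr(mask, "leaky")))
    stop("surface leaks: inconsistent ray-crossing parity")
  voxel_volume(array(mask, dim = n), pitch, lo)
}

# --- NRRD -----------------------------------------------------------------

#' Read and write NRRD volumes
#'
#' Minimal NRRD support for scalar volumes: raw little-endian or ascii
#' encodings, uint8/int16/int32/float/double types, with `space directions`
#' (voxel pitch) and `space origin` metadata.
#'
#' @param volume a [voxel_volume()] or numeric 3D array.
#' @param path file path.
#' @param encoding `"raw"` or `"ascii"`.
#' @param pitch,origin used when `volume` is a bare array.
#' @return `read_nrrd` returns a [voxel_volume()] (binary data) with the raw
#'   array in `$values` when non-binary.
#' @export
write_nrrd <- function(volume, path, encoding = c("raw", "ascii"),
                       pitch = NULL, origin = NULL) {
  encoding <- match.arg(encoding)
  if (inherits(volume, "voxel_volume")) {
    arr <- volume$mask + 0L; pitch <- volume$pitch; origin <- volume$origin
    type <- "uint8"
  } else {
    arr <- volume
    pitch <- pitch %||% c(1, 1, 1); origin <- origin %||% c(0, 0, 0)
    type <- "double"
  }
  dims <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("encoding: %s", encoding),
           "endian: little",
           "space: left-posterior-superior",
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   pitch[1], pitch[2], pitch[3]),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   origin[1], origin[2], origin[3]),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(as.vector(arr), collapse = " "), con)
  } else if (type == "uint8") {
    writeBin(as.integer(arr), con, size = 1L)
  } else {
    writeBin(as.numeric(arr), con, size = 8L)
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  type <- fields$type
  enc <- fields$encoding
  n <- prod(sizes)
  pitch <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    nums <- as.numeric(unlist(regmatches(fields[["space directions"]],
      gregexpr("-?[0-9.eE+-]+", fields[["space directions"]]))))
    m <- matrix(nums, 3, 3, byrow = TRUE)
    pitch <- sqrt(rowSums(m^2))
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(unlist(regmatches(fields[["space origin"]],
      gregexpr("-?[0-9.eE+-]+", fields[["space origin"]]))))
  if (enc == "ascii") {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    vals <- switch(type,
      uint8 = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
      int16 = readBin(con, "integer", n = n, size = 2L, endian = "little"),
      int32 = readBin(con, "integer", n = n, size = 4L, endian = "little"),
      float = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
      double = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
      stop("unsupported NRRD type: ", type))
  } else stop("unsupported NRRD encoding: ", enc)
  arr <- array(vals, dim = sizes)
  if (type %in% c("uint8", "int16", "int32") && all(arr %in% c(0, 1))) {
    voxel_volume(arr > 0, pitch, origin)
  } else {
    out <- voxel_volume(arr != 0, pitch, origin)
    out$values <- arr
    out
  }
}

#' Read a TIFF stack as a voxel volume
#'
#' @param path a multi-page TIFF file.
#' @param pitch voxel spacing (m), length 3.
#' @param threshold values above this (after 0-1 normalization) are
#'   foreground.
#' @return a [voxel_volume()].
#' @export
read_tiff_stack <- function(path, pitch, threshold = 0.5) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    t(p)[, rev(seq_len(nrow(p))), drop = FALSE]  # image rows -> y axis
  })
  arr <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  voxel_volume(arr > threshold, pitch)
}

#' Export a scalar field as a legacy-VTK structured-points file
#'
#' For slice rendering of velocity magnitude or concentration fields in
#' ParaView-like viewers.
#'
#' @param field numeric 3D array (cell data written as point data at cell
#'   centres).
#' @param path output `.vtk` path.
#' @param pitch,origin grid geometry (m).
#' @param name scalar name embedded in the file.
#' @export
write_vtk_field <- function(field, path, pitch, origin = c(0, 0, 0),
                            name = "field") {
  dims <- dim(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %.10g %.10g %.10g",
                       origin[1] + pitch[1] / 2, origin[2] + pitch[2] / 2,
                       origin[3] + pitch[3] / 2),
               sprintf("SPACING %.10g %.10g %.10g", pitch[1], pitch[2], pitch[3]),
               sprintf("POINT_DATA %d", prod(dims)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(paste(sprintf("%.8g", as.vector(field)), collapse = " "), con)
  invisible(path)
}
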