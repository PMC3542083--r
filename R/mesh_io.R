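#' Read and write colony meshes
#'
#' PLY (ascii or binary little-endian) and OFF input/output plus ascii STL
#' export.  Per-vertex scalar channels (absorbed flux, translocated
#' concentration, ...) are stored as extra float vertex properties in PLY
#' and round-trip through [read_ply()].
#'
#' @param surface a [tri_surface()].
#' @param path file path.
#' @param binary write binary little-endian PLY (default ascii).
#' @return `read_ply`/`read_off` return a [tri_surface()]; writers return
#'   the path invisibly.
#' @export
write_ply <- function(surface, path, binary = FALSE) {
  v <- surface$vertices
  f <- surface$faces
  ch <- surface$channels
  chnames <- names(ch)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment coralmorph colony surface",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           "property uchar boundary",
           sprintf("property double %s", chnames),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 8, endian = "little")
      writeBin(as.integer(surface$boundary[i]), con, size = 1)
      for (nm in chnames)
        writeBin(as.numeric(ch[[nm]][i]), con, size = 8, endian = "little")
    }
    for (i in seq_len(nrow(f))) {
      writeBin(3L, con, size = 1)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vm <- cbind(v, as.integer(surface$boundary))
    for (nm in chnames) vm <- cbind(vm, ch[[nm]])
    writeLines(apply(vm, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nv <- nf <- 0L
  vprops <- character(); vtypes <- character()
  element <- ""
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated PLY header")
    tok <- strsplit(trimws(line), " +")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      element <- tok[2]
      if (element == "vertex") nv <- as.integer(tok[3])
      if (element == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && element == "vertex" && tok[2] != "list") {
      vtypes <- c(vtypes, tok[2]); vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  sz <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
          int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
          float = 4, float32 = 4, double = 8, float64 = 8)
  if (fmt == "ascii") {
    vdat <- matrix(scan(con, what = double(), n = nv * length(vprops),
                        quiet = TRUE), nrow = nv, byrow = TRUE)
    fl <- readLines(con, n = nf)
    fdat <- t(vapply(strsplit(fl, " +"),
                     function(x) as.integer(x[2:4]), integer(3))) + 1L
  } else if (fmt == "binary_little_endian") {
    vdat <- matrix(0, nv, length(vprops))
    for (i in seq_len(nv))
      for (p in seq_along(vprops)) {
        type <- vtypes[p]
        vdat[i, p] <- if (type %in% c("float", "float32", "double", "float64"))
          readBin(con, "numeric", 1, size = sz[[type]], endian = "little")
        else readBin(con, "integer", 1, size = sz[[type]],
                     signed = !(sz[[type]] < 4 && grepl("^u", type)),
                     endian = "little")
      }
    fdat <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (cnt != 3) stop("non-triangular face in PLY")
      fdat[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  colnames(vdat) <- vprops
  xyz <- vdat[, c("x", "y", "z"), drop = FALSE]
  bnd <- if ("boundary" %in% vprops) vdat[, "boundary"] > 0 else NULL
  extra <- setdiff(vprops, c("x", "y", "z", "boundary", "nx", "ny", "nz"))
  ch <- if (length(extra)) {
    setNames(lapply(extra, function(nm) vdat[, nm]), extra)
  } else NULL
  tri_surface(xyz, fdat, boundary = bnd, channels = ch)
}

#' @rdname write_ply
#' @export
write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$vertices), nrow(surface$faces)),
             con)
  writeLines(apply(surface$vertices, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  f <- surface$faces
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), " +")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- t(vapply(strsplit(trimws(lines[3:(2 + nv)]), " +"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), " +"),
                function(x) as.integer(x[2:4]), integer(3))) + 1L
  tri_surface(v, f)
}

#' @rdname write_ply
#' @export
write_stl <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid colony", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[i, 1], a[i, 2], a[i, 3]),
                 sprintf("    vertex %g %g %g", b[i, 1], b[i, 2], b[i, 3]),
                 sprintf("    vertex %g %g %g", c3[i, 1], c3[i, 2], c3[i, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid colony", con)
  invisible(path)
}

#' Export per-vertex flux as CSV
#'
#' @param surface a [tri_surface()].
#' @param flux per-vertex values.
#' @param path output CSV path.
#' @export
write_flux_csv <- function(surface, flux, path) {
  write.csv(data.frame(vertex = seq_len(nrow(surface$vertices)),
                       x = surface$vertices[, 1], y = surface$vertices[, 2],
                       z = surface$vertices[, 3], flux = flux),
            path, row.names = FALSE)
  invisible(path)
}
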