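#' Triangulated colony surfaces
#'
#' A `tri_surface` is the growing colony: a triangulated 2-manifold whose
#' vertices stand for simulated polyps.  It stores vertex positions (m),
#' triangle index triples (1-based, counter-clockwise seen from outside),
#' per-vertex unit outward normals, a per-vertex boundary flag marking the
#' immobile rim where the colony is clipped by the substratum plane, and an
#' optional named list of per-vertex scalar channels (e.g. absorbed flux or
#' translocated nutrient concentration) that remeshing interpolates.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in metres.
#' @param faces integer matrix, m x 3, 1-based triangle vertex indices.
#' @param boundary logical vector of length n; `TRUE` for rim vertices fixed
#'   to the substratum.
#' @param channels named list of numeric vectors of length n, or `NULL`.
#' @param normals optional n x 3 matrix of unit outward normals; recomputed
#'   from the triangulation when omitted.
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, boundary = NULL, channels = NULL,
                        normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  n <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > n))
    stop("face indices out of range")
  if (is.null(boundary)) boundary <- rep(FALSE, n)
  stopifnot(length(boundary) == n)
  s <- structure(list(vertices = vertices, faces = faces,
                      boundary = as.logical(boundary),
                      channels = channels, normals = NULL),
                 class = "tri_surface")
  s$normals <- if (is.null(normals)) vertex_normals(s) else normals
  s
}

#' @export
print.tri_surface <- function(x, ...) {
  av <- try(surface_area_volume(x), silent = TRUE)
  cat(sprintf("<tri_surface> %d vertices, %d triangles, %d rim vertices\n",
              nrow(x$vertices), nrow(x$faces), sum(x$boundary)))
  if (!inherits(av, "try-error"))
    cat(sprintf("  area %.4g m^2, volume %.4g m^3\n", av[["area"]],
                av[["volume"]]))
  invisible(x)
}

# undirected edge list (each edge once) with face incidence counts
mesh_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  data.frame(a = pmin(e[first, 1], e[first, 2]),
             b = pmax(e[first, 1], e[first, 2]),
             nfaces = as.integer(tab[key[first]]))
}

edge_lengths <- function(surface, edges = mesh_edges(surface)) {
  v <- surface$vertices
  sqrt(rowSums((v[edges$a, , drop = FALSE] - v[edges$b, , drop = FALSE])^2))
}

# a mesh is 2-manifold (with boundary) when no edge has >2 incident faces
check_manifold <- function(surface, where = "surface") {
  ed <- mesh_edges(surface)
  if (any(ed$nfaces > 2L))
    stop(sprintf("%s is not 2-manifold: %d edges shared by >2 triangles",
                 where, sum(ed$nfaces > 2L)))
  invisible(ed)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Angle-weighted vertex normals
#'
#' Computes per-vertex unit normals as the angle-weighted average of the
#' incident triangle normals (the weight of a face at a vertex is the face's
#' interior angle there), then normalizes.  Each vertex advances along this
#' direction during accretion.
#'
#' @param surface a [tri_surface()].
#' @return an n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  deg <- tabulate(f, nbins = n)
  if (any(deg == 0L))
    stop("isolated vertex (no incident triangle): vertex ",
         paste(which(deg == 0L)[1]), call. = FALSE)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nrm <- sqrt(rowSums(fn^2))
  nrm[nrm == 0] <- 1
  fn <- fn / nrm
  ang <- function(p, q, r) {              # interior angle at p
    e1 <- q - p; e2 <- r - p
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)), .Machine$double.eps)
    acos(pmin(pmax(cosang, -1), 1))
  }
  wts <- cbind(ang(a, b, c3), ang(b, c3, a), ang(c3, a, b))
  out <- matrix(0, n, 3)
  for (corner in 1:3) {
    idx <- f[, corner]
    contrib <- fn * wts[, corner]
    for (d in 1:3) {
      acc <- rowsum(contrib[, d], idx)
      out[as.integer(rownames(acc)), d] <- out[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(out^2))
  if (any(len == 0))
    stop("degenerate normal at vertex ", which(len == 0)[1], call. = FALSE)
  out / len
}

# --- initial colony -------------------------------------------------------

# unit icosahedron (12 vertices, 20 faces, CCW outward)
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

# class-I geodesic sphere of frequency m: every icosahedron face is divided
# into m^2 triangles, points projected to the unit sphere; m gives fine
# control over the mean edge length (~1.2/m)
geodesic_sphere <- function(m) {
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  if (m == 1) return(ico)
  verts <- list(); faces <- list()
  vmap <- new.env(hash = TRUE)
  getv <- function(p) {
    p <- p / sqrt(sum(p^2))
    k <- paste(sprintf("%.9f", round(p, 9)), collapse = ",")
    id <- vmap[[k]]
    if (is.null(id)) {
      id <- length(verts) + 1L
      verts[[id]] <<- p
      vmap[[k]] <- id
    }
    id
  }
  for (t in seq_len(nrow(f))) {
    A <- v[f[t, 1], ]; B <- v[f[t, 2], ]; C <- v[f[t, 3], ]
    idg <- matrix(NA_integer_, m + 1, m + 1)
    for (i in 0:m)
      for (j in 0:(m - i))
        idg[i + 1, j + 1] <- getv(((m - i - j) * A + i * B + j * C) / m)
    for (i in 0:(m - 1))
      for (j in 0:(m - 1 - i)) {
        faces[[length(faces) + 1L]] <- c(idg[i + 1, j + 1], idg[i + 2, j + 1],
                                         idg[i + 1, j + 2])
        if (j < m - 1 - i)
          faces[[length(faces) + 1L]] <- c(idg[i + 2, j + 1], idg[i + 2, j + 2],
                                           idg[i + 1, j + 2])
      }
  }
  list(v = do.call(rbind, verts), f = do.call(rbind, faces))
}

# clamped spring relaxation that equalizes edge lengths while the projection
# callback keeps every vertex on its constraint manifold (sphere, rim circle)
relax_springs <- function(v, f, project, iters = 150, step = 0.3,
                          fixed = NULL, target_len = NULL) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  for (it in seq_len(iters)) {
    d <- v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    tgt <- target_len %||% mean(len)
    fv <- d * ((len - tgt) / pmax(len, 1e-300))
    F <- matrix(0, n, 3)
    for (dd in 1:3) {
      acc <- rowsum(fv[, dd], e[, 1])
      F[as.integer(rownames(acc)), dd] <- acc
    }
    mag <- sqrt(rowSums(F^2))
    F <- F * pmin(1, 0.05 * tgt / pmax(mag, 1e-300))
    if (!is.null(fixed)) F[fixed, ] <- 0
    v <- project(v + step * F)
  }
  v
}

# structured spherical-cap triangulation: latitude rings at near-equilateral
# spacing (sqrt(3)/2 * edge along the meridian), each ring sampled at the
# target edge length and stitched to the next by a two-pointer angular merge
ring_cap_mesh <- function(r, zc, substratum_z, te, center_xy) {
  cosmax <- pmin(pmax(-(zc - substratum_z) / r, -1), 1)
  theta_max <- acos(cosmax)                # colatitude of the rim
  nring <- max(3L, round(r * theta_max / (te * sqrt(3) / 2)))
  verts <- list(); ringids <- list(); ringang <- list()
  for (i in 0:nring) {
    th <- theta_max * (1 - i / nring)
    rho <- r * sin(th); z <- zc + r * cos(th)
    ni <- round(2 * pi * rho / te)
    if (i == nring || ni < 3) {            # pole vertex closes the cap
      ringids[[i + 1]] <- length(verts) + 1L
      ringang[[i + 1]] <- NA_real_
      verts[[length(verts) + 1]] <- c(0, 0, zc + r)
      break
    }
    ph <- (i %% 2) * pi / ni               # stagger alternate rings
    ang <- ph + 2 * pi * (0:(ni - 1)) / ni
    ids <- length(verts) + seq_len(ni)
    for (j in seq_len(ni))
      verts[[length(verts) + 1]] <- c(rho * cos(ang[j]), rho * sin(ang[j]), z)
    ringids[[i + 1]] <- ids; ringang[[i + 1]] <- ang
  }
  v <- do.call(rbind, verts)
  faces <- list()
  for (i in seq_len(length(ringids) - 1)) {
    L <- ringids[[i]]; U <- ringids[[i + 1]]
    aL <- ringang[[i]]; aU <- ringang[[i + 1]]
    nL <- length(L); nU <- length(U)
    if (nU == 1L) {
      for (j in seq_len(nL))
        faces[[length(faces) + 1]] <- c(L[j], L[j %% nL + 1], U)
      next
    }
    offs <- ((aU - aL[1]) + pi) %% (2 * pi) - pi
    j0 <- which.min(abs(offs))
    AL <- function(s) aL[(s %% nL) + 1] + 2 * pi * (s %/% nL)
    AU <- function(s) aU[((j0 - 1 + s) %% nU) + 1] +
      2 * pi * ((j0 - 1 + s) %/% nU) - (if (aU[j0] - aL[1] > pi) 2 * pi else 0)
    si <- 0; sj <- 0
    while (si < nL || sj < nU) {
      Lc <- L[(si %% nL) + 1]; Ln <- L[((si + 1) %% nL) + 1]
      Uc <- U[((j0 - 1 + sj) %% nU) + 1]; Un <- U[((j0 + sj) %% nU) + 1]
      advL <- sj >= nU || (si < nL && AL(si + 1) <= AU(sj + 1))
      if (advL) {
        faces[[length(faces) + 1]] <- c(Lc, Ln, Uc); si <- si + 1
      } else {
        faces[[length(faces) + 1]] <- c(Un, Uc, Lc); sj <- sj + 1
      }
    }
  }
  f <- do.call(rbind, faces)
  bnd <- logical(nrow(v)); bnd[ringids[[1]]] <- TRUE
  v[, 1] <- v[, 1] + center_xy[1]
  v[, 2] <- v[, 2] + center_xy[2]
  list(v = v, f = f, boundary = bnd)
}

# outlier-focused relaxation: forces act only on edges outside the +-margin
# band around the target length, so the equilibrium has every edge in band
relax_hinge <- function(v, f, te, project, iters = 300, margin = 0.13,
                        step = 0.25) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  for (it in seq_len(iters)) {
    d <- v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    dev <- pmax(0, len - (1 + margin) * te) + pmin(0, len - (1 - margin) * te)
    fv <- d * (dev / pmax(len, 1e-300))
    F <- matrix(0, n, 3)
    for (dd in 1:3) {
      acc <- rowsum(fv[, dd], e[, 1])
      F[as.integer(rownames(acc)), dd] <- acc
    }
    mag <- sqrt(rowSums(F^2))
    F <- F * pmin(1, 0.05 * te / pmax(mag, 1e-300))
    v <- project(v + step * F)
  }
  v
}

#' Construct the initial colony
#'
#' Builds a triangulated sphere of the given diameter sitting on the
#' substratum plane, which truncates it `clip_fraction * diameter` below the
#' sphere centre (default 1/6).  The cap is laid out on latitude rings at
#' near-uniform spacing, polished by spring relaxation, valence-regularizing
#' edge flips and an outlier-focused pass, so every edge ends up within about
#' 20% of `target_edge`.  Rim vertices on the plane are flagged as immobile
#' anchors.
#'
#' @param diameter sphere diameter in metres (default 0.06).
#' @param substratum_z z coordinate of the substratum plane (default 0).
#' @param target_edge desired mean edge length in metres.
#' @param center_xy numeric length-2, x/y position of the sphere centre.
#' @param clip_fraction how far below the centre (as a fraction of the
#'   diameter) the substratum cuts the sphere; 0 clips at the equator
#'   (hemisphere).
#' @return a [tri_surface()] whose rim vertices are flagged `boundary`.
#' @export
make_initial_colony <- function(diameter = 0.06, substratum_z = 0,
                                target_edge = diameter / 15,
                                center_xy = c(0, 0), clip_fraction = 1 / 6) {
  if (diameter <= 0) stop("diameter must be positive")
  if (target_edge >= diameter / 4)
    stop("target_edge too large to form a closed sphere: need target_edge < diameter/4")
  if (clip_fraction < 0 || clip_fraction >= 0.5)
    stop("clip_fraction must lie in [0, 0.5): 0 clips at the equator")
  r <- diameter / 2
  zc <- substratum_z + clip_fraction * diameter
  g <- ring_cap_mesh(r, zc, substratum_z, target_edge, center_xy)
  s <- tri_surface(g$v, g$f, boundary = g$boundary)
  rim_r <- sqrt(max(r^2 - (zc - substratum_z)^2, 1e-300))
  make_project <- function(bnd) {
    force(bnd)
    function(x) {
      int <- !bnd
      d <- sweep(x[int, , drop = FALSE], 2, c(center_xy, zc))
      x[int, ] <- sweep(d * (r / sqrt(rowSums(d^2))), 2, c(center_xy, zc), "+")
      if (any(bnd)) {
        rxy <- x[bnd, 1:2, drop = FALSE] -
          matrix(center_xy, sum(bnd), 2, byrow = TRUE)
        rn <- sqrt(rowSums(rxy^2))
        x[bnd, 1:2] <- rxy * (rim_r / pmax(rn, 1e-300)) +
          matrix(center_xy, sum(bnd), 2, byrow = TRUE)
        x[bnd, 3] <- substratum_z
      }
      x
    }
  }
  for (pass in 1:4) {
    sp <- remesh_split_pass(s, 1.25 * target_edge)
    co <- remesh_collapse_pass(sp$surface, 0.78 * target_edge)
    fl <- remesh_flip_pass(co$surface)
    s <- fl$surface
    project <- make_project(s$boundary)
    v2 <- relax_springs(s$vertices, s$faces, project, iters = 100)
    s <- tri_surface(v2, s$faces, boundary = s$boundary)
    len <- edge_lengths(s)
    if (min(len) >= 0.85 * target_edge && max(len) <= 1.15 * target_edge) break
  }
  # outlier surgery: persistent long edges mark a local vertex deficit, so
  # split them and let the hinge relaxation absorb the new vertex
  for (hp in 1:6) {
    len <- edge_lengths(s)
    if (min(len) >= 0.8 * target_edge && max(len) <= 1.2 * target_edge) break
    sp <- remesh_split_pass(s, 1.18 * target_edge)
    s <- sp$surface
    v2 <- relax_hinge(s$vertices, s$faces, target_edge,
                      make_project(s$boundary), iters = 400)
    s <- tri_surface(v2, s$faces, boundary = s$boundary)
    if (min(edge_lengths(s)) < 0.8 * target_edge) {
      co <- remesh_collapse_pass(s, 0.8 * target_edge)
      fl <- remesh_flip_pass(co$surface)
      s <- fl$surface
      v2 <- relax_hinge(s$vertices, s$faces, target_edge,
                        make_project(s$boundary), iters = 400)
      s <- tri_surface(v2, s$faces, boundary = s$boundary)
    }
  }
  mean_e <- mean(edge_lengths(s))
  if (abs(mean_e - target_edge) > 0.2 * target_edge)
    warning(sprintf("mean edge length %.3g deviates >20%% from target %.3g",
                    mean_e, target_edge))
  s
}

#' Apply an accretive growth layer
#'
#' Displaces every vertex along its stored outward normal by the per-vertex
#' extension length: `v_i' = v_i + l_i * n_i`.  Rim (substratum-anchored)
#' vertices never move.  Topology is unchanged; call [remesh()] afterwards to
#' insert triangles where the surface has stretched.
#'
#' @param surface a [tri_surface()].
#' @param lengths numeric vector of per-vertex extension lengths (m), all
#'   `>= 0`, one per vertex.
#' @param check_intersection if `TRUE`, test the displaced surface for
#'   triangle-triangle self-intersection (the physical analogue of branch
#'   fusion, which the model does not simulate) and record the result in
#'   `attr(, "self_intersections")`.
#' @return the displaced `tri_surface`; normals are recomputed.
#' @export
accrete <- function(surface, lengths, check_intersection = FALSE) {
  n <- nrow(surface$vertices)
  if (length(lengths) != n)
    stop("lengths must match vertex count (", n, ")")
  if (any(lengths < 0)) stop("negative extension length")
  l <- lengths
  l[surface$boundary] <- 0
  v2 <- surface$vertices + surface$normals * l
  out <- tri_surface(v2, surface$faces, boundary = surface$boundary,
                     channels = surface$channels)
  if (check_intersection) {
    hits <- cpp_self_intersections(out$vertices, out$faces)
    attr(out, "self_intersections") <- hits
  }
  out
}

#' Isotropic remeshing by edge split and collapse
#'
#' Splits every edge longer than `1.5 * target_edge` at its midpoint (the new
#' vertex inherits the arithmetic mean of the endpoint channel values) and
#' collapses every interior edge shorter than `0.5 * target_edge` whose
#' collapse preserves manifoldness.  Collapses that would pinch the mesh are
#' skipped and counted in `attr(, "skipped_collapses")`.
#'
#' @param surface a [tri_surface()].
#' @param target_edge target edge length (m).
#' @param max_passes maximum split/collapse sweeps.
#' @return a manifold `tri_surface` with edges in roughly
#'   `[0.5, 1.5] * target_edge`.
#' @export
remesh <- function(surface, target_edge, max_passes = 10) {
  check_manifold(surface, "remesh input")
  skipped <- 0L
  for (pass in seq_len(max_passes)) {
    res <- remesh_split_pass(surface, 1.5 * target_edge)
    surface <- res$surface
    res2 <- remesh_collapse_pass(surface, 0.5 * target_edge)
    surface <- res2$surface
    skipped <- skipped + res2$skipped
    if (res$nsplit == 0L && res2$ncollapse == 0L) break
  }
  check_manifold(surface, "remesh output")
  attr(surface, "skipped_collapses") <- skipped
  surface
}

remesh_split_pass <- function(surface, max_len) {
  ed <- mesh_edges(surface)
  len <- edge_lengths(surface, ed)
  long <- which(len > max_len)
  if (!length(long)) return(list(surface = surface, nsplit = 0L))
  v <- surface$vertices; f <- surface$faces
  n <- nrow(v)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  splitmap <- new.env(hash = TRUE)
  newv <- vector("list", length(long))
  newb <- logical(length(long))
  for (i in seq_along(long)) {
    a <- ed$a[long[i]]; b <- ed$b[long[i]]
    newv[[i]] <- (v[a, ] + v[b, ]) / 2
    # midpoint is rim only if it subdivides a rim (single-face) edge
    newb[i] <- surface$boundary[a] && surface$boundary[b] &&
      ed$nfaces[long[i]] == 1L
    assign(key(a, b), n + i, envir = splitmap)
  }
  v2 <- rbind(v, do.call(rbind, newv))
  bnd2 <- c(surface$boundary, newb)
  ch2 <- lapply(surface$channels, function(x) {
    c(x, vapply(seq_along(long),
                function(i) (x[ed$a[long[i]]] + x[ed$b[long[i]]]) / 2, 0))
  })
  get_mid <- function(i, j) {
    id <- splitmap[[key(i, j)]]
    if (is.null(id)) NA_integer_ else id
  }
  out <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
    mab <- get_mid(a, b); mbc <- get_mid(b, c3); mca <- get_mid(c3, a)
    ns <- sum(!is.na(c(mab, mbc, mca)))
    out[[t]] <- if (ns == 0) {
      rbind(c(a, b, c3))
    } else if (ns == 3) {
      rbind(c(a, mab, mca), c(b, mbc, mab), c(c3, mca, mbc), c(mab, mbc, mca))
    } else if (ns == 1) {
      if (!is.na(mab)) rbind(c(a, mab, c3), c(mab, b, c3))
      else if (!is.na(mbc)) rbind(c(b, mbc, a), c(mbc, c3, a))
      else rbind(c(c3, mca, b), c(mca, a, b))
    } else {                               # two edges split
      if (is.na(mab)) rbind(c(c3, mca, mbc), c(mca, b, mbc), c(mca, a, b))
      else if (is.na(mbc)) rbind(c(a, mab, mca), c(mab, c3, mca), c(mab, b, c3))
      else rbind(c(b, mbc, mab), c(mbc, a, mab), c(mbc, c3, a))
    }
  }
  f2 <- do.call(rbind, out)
  s2 <- tri_surface(v2, f2, boundary = bnd2, channels = ch2)
  list(surface = s2, nsplit = length(long))
}

remesh_collapse_pass <- function(surface, min_len) {
  ed <- mesh_edges(surface)
  len <- edge_lengths(surface, ed)
  short <- order(len)[len[order(len)] < min_len]
  if (!length(short)) return(list(surface = surface, ncollapse = 0L, skipped = 0L))
  v <- surface$vertices; f <- surface$faces
  n <- nrow(v)
  # vertex adjacency (one-ring) for the link condition
  ee <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
              f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  nbr <- split(ee[, 2], ee[, 1])
  nbr <- lapply(nbr, unique)
  touched <- logical(n)
  remap <- seq_len(n)
  keep_pos <- v
  bnd <- surface$boundary
  ch <- surface$channels
  ncol_done <- 0L; skipped <- 0L
  for (i in short) {
    a <- ed$a[i]; b <- ed$b[i]
    if (touched[a] || touched[b]) next
    common <- intersect(nbr[[as.character(a)]], nbr[[as.character(b)]])
    if (bnd[a] && bnd[b]) {
      # rim edge: collapse along the rim only (midpoint stays on the
      # substratum plane); rim chords would pinch the surface
      if (ed$nfaces[i] != 1L || length(common) != 1L) { skipped <- skipped + 1L; next }
      keep_pos[a, ] <- (v[a, ] + v[b, ]) / 2
    } else if (bnd[a] || bnd[b]) {
      # absorb the interior endpoint into the rim vertex (rim stays put)
      if (length(common) != 2L) { skipped <- skipped + 1L; next }
      if (bnd[b]) { tmp <- a; a <- b; b <- tmp }
      keep_pos[a, ] <- v[a, ]
    } else {
      if (length(common) != 2L) { skipped <- skipped + 1L; next }  # link condition
      keep_pos[a, ] <- (v[a, ] + v[b, ]) / 2
    }
    remap[b] <- a
    if (!is.null(ch)) for (nm in names(ch)) ch[[nm]][a] <- (ch[[nm]][a] + ch[[nm]][b]) / 2
    touched[c(a, b, common)] <- TRUE
    ncol_done <- ncol_done + 1L
  }
  if (ncol_done == 0L)
    return(list(surface = surface, ncollapse = 0L, skipped = skipped))
  f2 <- matrix(remap[f], ncol = 3)
  degen <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  f2 <- f2[!degen, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  idx <- integer(n); idx[used] <- seq_along(used)
  v2 <- keep_pos[used, , drop = FALSE]
  f2 <- matrix(idx[f2], ncol = 3)
  bnd2 <- bnd[used]
  ch2 <- if (is.null(ch)) NULL else lapply(ch, function(x) x[used])
  s2 <- tri_surface(v2, f2, boundary = bnd2, channels = ch2)
  list(surface = s2, ncollapse = ncol_done, skipped = skipped)
}

# valence-regularizing edge flips (target vertex valence 6 interior / 4 rim);
# flipping edge (a,b) with opposite vertices (c,d) replaces triangles
# (a,b,c),(b,a,d) by (a,d,c),(d,b,c)
remesh_flip_pass <- function(surface) {
  f <- surface$faces
  n <- nrow(surface$vertices)
  val <- tabulate(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])[, 1],
                  nbins = n)   # edge valence = directed-edge out-degree
  tgt <- ifelse(surface$boundary, 3, 6)   # face-count targets (rim ~180deg/60deg)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nrow(f)), 3)
  corner <- rep(1:3, each = nrow(f))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(key)
  adjkey <- unique(key)
  # adjacency set for duplicate-edge guard
  nbr <- new.env(hash = TRUE)
  for (k in adjkey) nbr[[k]] <- TRUE
  sp <- split(seq_len(length(key)), key)
  ftouch <- logical(nrow(f))
  nflip <- 0L
  for (k in names(sp)) {
    rows <- sp[[k]]
    if (length(rows) != 2L) next
    t1 <- fid[rows[1]]; t2 <- fid[rows[2]]
    if (ftouch[t1] || ftouch[t2]) next
    a <- e[rows[1], 1]; b <- e[rows[1], 2]
    c3 <- setdiff(f[t1, ], c(a, b)); d <- setdiff(f[t2, ], c(a, b))
    if (length(c3) != 1L || length(d) != 1L || c3 == d) next
    kk <- paste(min(c3, d), max(c3, d))
    if (!is.null(nbr[[kk]])) next          # c-d already an edge
    dev0 <- (val[a] - tgt[a])^2 + (val[b] - tgt[b])^2 +
      (val[c3] - tgt[c3])^2 + (val[d] - tgt[d])^2
    dev1 <- (val[a] - 1 - tgt[a])^2 + (val[b] - 1 - tgt[b])^2 +
      (val[c3] + 1 - tgt[c3])^2 + (val[d] + 1 - tgt[d])^2
    if (dev1 >= dev0) next
    if (val[a] <= 3 || val[b] <= 3) next
    f[t1, ] <- c(a, d, c3)
    f[t2, ] <- c(d, b, c3)
    val[a] <- val[a] - 1L; val[b] <- val[b] - 1L
    val[c3] <- val[c3] + 1L; val[d] <- val[d] + 1L
    nbr[[kk]] <- TRUE
    ftouch[c(t1, t2)] <- TRUE
    nflip <- nflip + 1L
  }
  s2 <- tri_surface(surface$vertices, f, boundary = surface$boundary,
                    channels = surface$channels)
  list(surface = s2, nflip = nflip)
}

#' Surface area and enclosed volume
#'
#' Area is the sum of colony triangle areas (the living surface; the
#' substratum cap is excluded).  Volume is computed with the divergence
#' theorem after closing the rim with a triangle fan, so a colony clipped by
#' the substratum is treated as capped by the plane it sits on.
#'
#' @param surface a [tri_surface()].
#' @return named numeric vector with elements `area` (m^2), `volume` (m^3)
#'   and `sv_ratio` (m^-1).
#' @export
surface_area_volume <- function(surface) {
  ed <- check_manifold(surface)
  v <- surface$vertices; f <- surface$faces
  area <- sum(triangle_areas(v, f))
  bed <- ed[ed$nfaces == 1L, , drop = FALSE]
  fall <- f
  if (nrow(bed) > 0) {
    rim <- unique(c(bed$a, bed$b))
    if (!all(surface$boundary[rim]))
      stop("open surface without substratum cap: boundary edges off the rim")
    cen_id <- nrow(v) + 1L
    v <- rbind(v, colMeans(v[rim, , drop = FALSE]))
    # boundary directed edges appear once in the face list; cap with the
    # reversed direction to keep a consistent outward orientation
    dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keyd <- paste(dir_e[, 1], dir_e[, 2])
    keyu <- paste(pmin(dir_e[, 1], dir_e[, 2]), pmax(dir_e[, 1], dir_e[, 2]))
    single <- keyu %in% paste(bed$a, bed$b)
    bdir <- dir_e[single, , drop = FALSE]
    caps <- cbind(bdir[, 2], bdir[, 1], cen_id)
    fall <- rbind(f, caps)
  }
  a <- v[fall[, 1], , drop = FALSE]
  b <- v[fall[, 2], , drop = FALSE]
  c3 <- v[fall[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
             a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
             a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  if (vol < 0)
    stop("negative signed volume: surface orientation is inward")
  c(area = area, volume = vol, sv_ratio = area / vol)
}

#' Maximum linear extent of a colony
#'
#' Returns the largest axis-aligned bounding-box extent of the final surface
#' in a growth history (or of a single surface), the size measure used to
#' check that a full simulation reaches a realistic colony scale.
#'
#' @param history a `tri_surface`, or a list of them (a growth history).
#' @return length in metres.
#' @export
colony_extension_check <- function(history) {
  s <- if (inherits(history, "tri_surface")) history else history[[length(history)]]
  stopifnot(inherits(s, "tri_surface"))
  max(apply(s$vertices, 2, function(x) diff(range(x))))
}
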