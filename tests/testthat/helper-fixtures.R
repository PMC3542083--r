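# shared builders for solver and morphometry tests; everything is generated
# in code so the suite needs no binary fixtures

# closed unit icosphere (no substratum clip)
make_icosphere <- function(subdiv = 3, radius = 1) {
  g <- coralmorph:::geodesic_sphere(2^subdiv)
  tri_surface(g$v * radius, g$f)
}

# solid axis-aligned cylinder volume with flat caps, padded by empty voxels
make_cylinder_volume <- function(diameter_vox = 12, length_vox = 48,
                                 pitch = 1e-3, pad = 6) {
  r <- diameter_vox / 2
  nxy <- 2 * ceiling(r) + 2 * pad + 1
  nz <- length_vox + 2 * pad
  cc <- (nxy + 1) / 2
  mask <- array(FALSE, c(nxy, nxy, nz))
  disc <- outer(seq_len(nxy), seq_len(nxy),
                function(i, j) (i - cc)^2 + (j - cc)^2 <= (r + 0.01)^2)
  for (k in (pad + 1):(pad + length_vox)) mask[, , k] <- disc
  voxel_volume(mask, rep(pitch, 3))
}

# solid Y: vertical trunk splitting into two oblique arms (capsule union)
make_y_volume <- function(radius = 3e-3, pitch = 1e-3) {
  segs <- list(rbind(c(0, 0, 0), c(0, 0, 0.025)),
               rbind(c(0, 0, 0.025), c(0.02, 0, 0.05)),
               rbind(c(0, 0, 0.025), c(-0.02, 0, 0.05)))
  lo <- c(-0.03, -0.01, 0); hi <- c(0.03, 0.01, 0.056)
  n <- ceiling((hi - lo) / pitch)
  xs <- lo[1] + (seq_len(n[1]) - 0.5) * pitch
  ys <- lo[2] + (seq_len(n[2]) - 0.5) * pitch
  zs <- lo[3] + (seq_len(n[3]) - 0.5) * pitch
  X <- array(rep(xs, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)
  mask <- array(FALSE, dim = n)
  for (s in segs) {
    a <- s[1, ]; d <- s[2, ] - s[1, ]; L <- sqrt(sum(d^2)); d <- d / L
    t <- pmin(pmax((X - a[1]) * d[1] + (Y - a[2]) * d[2] + (Z - a[3]) * d[3], 0), L)
    dist2 <- (X - a[1] - t * d[1])^2 + (Y - a[2] - t * d[2])^2 +
      (Z - a[3] - t * d[3])^2
    mask <- mask | dist2 <= radius^2
  }
  voxel_volume(mask, rep(pitch, 3))
}

# hand-built two-node skeleton graph for the symmetry-angle worked examples
make_toy_skeleton <- function(offsets, root = c(0, 0, 0), radius = 1e-3) {
  nodes <- data.frame(x = c(root[1], root[1] + offsets[, 1]),
                      y = c(root[2], root[2] + offsets[, 2]),
                      z = c(root[3], root[3] + offsets[, 3]),
                      radius = radius,
                      degree = c(nrow(offsets), rep(1L, nrow(offsets))),
                      endpoint = c(FALSE, rep(TRUE, nrow(offsets))))
  nodes$root <- c(TRUE, rep(FALSE, nrow(offsets)))
  g <- list(nodes = nodes,
            edges = data.frame(from = 1L, to = 2:(nrow(offsets) + 1),
                               length = sqrt(rowSums(offsets^2))),
            paths = list(), root = 1L, pitch = rep(1e-9, 3),
            voxel_index = matrix(1L, nrow(offsets) + 1, 3))
  class(g) <- "skeleton_graph"
  g
}

# brute-force angle-weighted vertex-normal accumulation (independent oracle)
normals_oracle <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  out <- matrix(0, nrow(v), 3)
  for (t in seq_len(nrow(f))) {
    tri <- f[t, ]
    p <- v[tri, ]
    fn <- pracma::cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    fn <- fn / sqrt(sum(fn^2))
    for (c1 in 1:3) {
      e1 <- p[c1 %% 3 + 1, ] - p[c1, ]
      e2 <- p[(c1 + 1) %% 3 + 1, ] - p[c1, ]
      ang <- acos(sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2)))
      out[tri[c1], ] <- out[tri[c1], ] + ang * fn
    }
  }
  out / sqrt(rowSums(out^2))
}

# small channel domain used across flow/transport tests
small_channel <- function(n = c(30, 30, 20), extent = c(0.3, 0.3, 0.2)) {
  simulation_domain(extent = extent, n = n)
}
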