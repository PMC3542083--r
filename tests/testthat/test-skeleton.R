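test_that("a solid cylinder reduces to a single medial path", {
  vol <- make_cylinder_volume(diameter_vox = 12, length_vox = 48)
  sk <- skeletonize(vol)
  # two tips: the lower one anchors the root, one free endpoint remains
  expect_equal(sum(sk$nodes$degree <= 1L), 2L)
  expect_equal(coralmorph:::skeleton_cycles(sk), 0L)
  tt <- terminal_thickness(sk, vol)
  expect_equal(tt$mean_dc, 12e-3, tolerance = 1 / 12)   # within one voxel
})

test_that("a solid Y has one junction and three tips", {
  vol <- make_y_volume()
  sk <- skeletonize(vol)
  expect_equal(sum(sk$nodes$degree <= 1L), 3L)
  expect_equal(sum(sk$nodes$degree >= 3L), 1L)
  expect_equal(coralmorph:::skeleton_cycles(sk), 0L)
})

test_that("branch-count ground truth is recovered on procedural fixtures", {
  for (seed in c(1L, 2L, 4L)) {
    fx <- suppressWarnings(
      make_branching_volume(fixture_spec(n_branches = 8, seed = seed)))
    sk <- skeletonize(fx$volume)
    expect_equal(sum(sk$nodes$endpoint & !sk$nodes$root), 8L)
  }
  fx3 <- suppressWarnings(
    make_branching_volume(fixture_spec(n_branches = 3, elevation_deg = 50,
                                       seed = 2)))
  sk3 <- skeletonize(fx3$volume)
  expect_equal(sum(sk3$nodes$endpoint & !sk3$nodes$root), 3L)
})

test_that("skeletonization preserves loops (first Betti number)", {
  # solid torus: one independent cycle
  n <- 48
  mask <- array(FALSE, c(n, n, 17))
  for (k in 1:17)
    mask[, , k] <- outer(seq_len(n), seq_len(n), function(i, j) {
      rr <- sqrt((i - 24.5)^2 + (j - 24.5)^2)
      (rr - 14)^2 + (k - 9)^2 <= 5^2
    })
  skt <- skeletonize(voxel_volume(mask, rep(1e-3, 3)), prune_factor = 0)
  expect_equal(coralmorph:::skeleton_cycles(skt), 1L)
  # trees stay trees
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 1)))
  expect_equal(coralmorph:::skeleton_cycles(skeletonize(fx$volume)), 0L)
})

test_that("the skeleton is stable under 90-degree rotation about z", {
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 2)))
  sk <- skeletonize(fx$volume)
  m <- fx$volume$mask
  m2 <- aperm(m[dim(m)[1]:1, , , drop = FALSE], c(2, 1, 3))
  vol2 <- voxel_volume(m2, fx$volume$pitch[c(2, 1, 3)])
  sk2 <- skeletonize(vol2)
  expect_equal(sum(sk2$nodes$endpoint & !sk2$nodes$root),
               sum(sk$nodes$endpoint & !sk$nodes$root))
  expect_equal(coralmorph:::skeleton_cycles(sk2),
               coralmorph:::skeleton_cycles(sk))
  # endpoint positions agree within one voxel after rotating back
  rot_back <- function(p, vol) {
    # inverse of (i,j) -> (nj - j + 1 -> ...) mapping in physical space
    nx <- dim(vol$mask)[2] * vol$pitch[2]
    cbind(p[, 2], nx - (p[, 1] - vol$origin[1]) + vol$origin[1], p[, 3])
  }
  e1 <- as.matrix(sk$nodes[sk$nodes$endpoint & !sk$nodes$root,
                           c("x", "y", "z")])
  e2 <- as.matrix(sk2$nodes[sk2$nodes$endpoint & !sk2$nodes$root,
                            c("x", "y", "z")])
  # sorted tip heights agree within about one voxel
  expect_lt(max(abs(sort(e1[, 3]) - sort(e2[, 3]))), 1.2e-3)
})

test_that("multi-component volumes are rejected with guidance", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:4, 2:4, 2:4] <- TRUE
  mask[8:10, 8:10, 8:10] <- TRUE
  expect_error(skeletonize(voxel_volume(mask, rep(1e-3, 3))),
               "largest_component")
  vol <- largest_component(voxel_volume(mask, rep(1e-3, 3)))
  expect_equal(sum(vol$mask), 27L)
})

test_that("skeleton export writes GraphML and edge CSV", {
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 1)))
  sk <- skeletonize(fx$volume)
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  write_skeleton_graphml(sk, gml, edge_csv = csv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(sk$nodes))
  expect_equal(nrow(read.csv(csv)), nrow(sk$edges))
})
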