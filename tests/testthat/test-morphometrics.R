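test_that("terminal thickness recovers cylinder diameters within one voxel", {
  for (dvox in c(6, 12, 20)) {
    vol <- make_cylinder_volume(diameter_vox = dvox, length_vox = 44)
    sk <- skeletonize(vol)
    tt <- terminal_thickness(sk, vol)
    expect_equal(tt$mean_dc / 1e-3, dvox, tolerance = 1 / dvox)
  }
})

test_that("mean dc recovers the known branch radii of a fixture", {
  sp <- fixture_spec(n_branches = 3, radius_range = c(2e-3, 3e-3, 4e-3),
                     elevation_deg = 50, length_range = c(0.035, 0.035),
                     pitch = 0.75e-3, seed = 2)
  fx <- suppressWarnings(make_branching_volume(sp))
  sk <- skeletonize(fx$volume)
  tt <- terminal_thickness(sk, fx$volume)
  expect_equal(length(tt$dc), 3L)
  expect_equal(tt$mean_dc, 6e-3, tolerance = 0.75e-3 / 6e-3)  # +-1 voxel
})

test_that("branchless solids report the degenerate-skeleton error", {
  mask <- array(FALSE, c(17, 17, 17))      # digital ball, no branches
  for (k in 1:17)
    mask[, , k] <- outer(1:17, 1:17, function(i, j)
      (i - 9)^2 + (j - 9)^2 + (k - 9)^2 <= 5.2^2)
  vol <- voxel_volume(mask, rep(1e-3, 3))
  sk <- skeletonize(vol)
  expect_error(terminal_thickness(sk, vol), "no terminal branches")
})

test_that("symmetry angles follow the plane-projection worked examples", {
  toy <- make_toy_skeleton(rbind(c(1, 0, 1) / sqrt(2)))
  a <- symmetry_angles(toy, flow_axis = c(1, 0, 0))
  expect_equal(a$h_angle, 45, tolerance = 1e-9)
  expect_equal(a$v_angle, 45, tolerance = 1e-9)
  expect_equal(a$h_angle + a$v_angle, 90, tolerance = 1e-9)
  a2 <- symmetry_angles(make_toy_skeleton(rbind(c(1, 0, 0))))
  expect_equal(a2$h_angle, 0, tolerance = 1e-9)
  expect_equal(a2$v_angle, 90, tolerance = 1e-9)
  a3 <- symmetry_angles(make_toy_skeleton(rbind(c(0, 1, 0))))
  expect_equal(a3$h_angle, 0, tolerance = 1e-9)
  expect_equal(a3$v_angle, 0, tolerance = 1e-9)
  expect_error(symmetry_angles(toy, flow_axis = c(0, 0, 1)), "orthogonal")
})

test_that("symmetry magnitude negates for mirror-opposed nodes", {
  toy <- make_toy_skeleton(rbind(c(-0.02, 0.01, 0.03), c(0.02, -0.01, 0.03)))
  sm <- symmetry_magnitude(toy, upstream_ref = c(-1, 0, 0))
  expect_equal(sm$signed_sum, 0, tolerance = 1e-12)
  # all-upstream cluster: signed mean positive, magnitude ~ mean |d|
  up <- make_toy_skeleton(rbind(c(-0.03, 0, 0), c(-0.02, 0, 0)))
  smu <- symmetry_magnitude(up, upstream_ref = c(-1, 0, 0))
  expect_gt(smu$signed_mean, 0)
  expect_equal(smu$mean_magnitude, 0.025, tolerance = 1e-9)
  expect_error(symmetry_magnitude(toy, upstream_ref = c(0, 0, 5)),
               "degenerate")
})

test_that("isotropic 45-degree fixtures read back as symmetric", {
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 2)))
  sk <- skeletonize(fx$volume)
  ang <- symmetry_angles(sk)
  expect_equal(ang$mean_h, 45, tolerance = 3 / 45)
  sm <- symmetry_magnitude(sk, upstream_ref = c(-1, 0, 0))
  expect_lt(abs(sm$signed_mean), 1e-3)     # below one voxel pitch
})

test_that("orientation bias raises the signed symmetry magnitude monotonically", {
  sms <- vapply(c(0, 0.5, 0.9), function(b) {
    fx <- suppressWarnings(
      make_branching_volume(fixture_spec(bias = b, seed = 3)))
    symmetry_magnitude(skeletonize(fx$volume),
                       upstream_ref = c(-1, 0, 0))$signed_mean
  }, 0)
  expect_true(all(diff(sms) > 0))
})

test_that("angle statistics match the textbook formulas", {
  x <- c(12.1, 44.9, 30.2, 61.5, 28.4, 39.9, 51.2, 47.8, 25.3, 33.6,
         58.2, 41.7, 36.8, 49.5, 22.9, 55.1, 31.4, 46.3, 38.2, 43.7)
  st <- angle_distribution_stats(x)
  n <- length(x); m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)   # adjusted Fisher-Pearson
  g2 <- mean((x - m)^4) / (mean((x - m)^2))^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(st$skewness, G1, tolerance = 1e-12)
  expect_equal(st$kurtosis, G2, tolerance = 1e-12)
  expect_equal(st$mean, m)
  expect_equal(st$ci[2] - st$ci[1],
               2 * qt(0.975, n - 1) * s / sqrt(n), tolerance = 1e-12)
  # symmetric pairs around the mean have zero skewness
  expect_equal(angle_distribution_stats(c(40, 50, 42, 48, 45 - 3, 45 + 3))$skewness,
               0, tolerance = 1e-12)
  expect_error(angle_distribution_stats(rep(45, 10)), "zero variance")
  expect_error(angle_distribution_stats(c(1, 2)), "at least 3")
})

test_that("morph reports recompute Pe and Re from their configuration", {
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 1)))
  rep <- morph_report(fx$volume, u_mean = 0.05, D = 1e-1, mu = 5e-2,
                      rho = 1000)
  expect_equal(rep$pe_branch, 0.05 * rep$dc / 1e-1)
  expect_equal(rep$re_branch, 1000 * 0.05 * rep$dc / 5e-2)
  expect_true(all(c("sv_ratio", "sm_mag_mean", "h_angle_mean",
                    "h_skewness", "h_kurtosis") %in% names(rep)))
})

test_that("mesh input reuses the exact mesh area and volume", {
  col <- make_initial_colony(0.06, 0, 0.004)
  av <- surface_area_volume(col)
  rep <- morph_report(col, pitch = 1.5e-3)
  expect_identical(rep$surface_area, av[["area"]])
  expect_identical(rep$volume, av[["volume"]])
  expect_equal(rep$sv_ratio, av[["sv_ratio"]])
})

test_that("voxel and divergence-theorem volumes agree at fine pitch", {
  col <- make_initial_colony(0.06, 0, 0.004)
  vol <- mesh_to_volume(col, 1.5e-3)
  expect_equal(sum(vol$mask) * prod(vol$pitch),
               surface_area_volume(col)[["volume"]], tolerance = 0.1)
})
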