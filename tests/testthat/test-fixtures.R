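test_that("the generator is bit-reproducible per seed and varies across seeds", {
  f1 <- suppressWarnings(make_branching_volume(fixture_spec(seed = 7)))
  f2 <- suppressWarnings(make_branching_volume(fixture_spec(seed = 7)))
  expect_identical(f1$volume$mask, f2$volume$mask)
  expect_identical(f1$truth, f2$truth)
  f3 <- suppressWarnings(make_branching_volume(fixture_spec(seed = 8)))
  expect_false(identical(f1$truth$tip_x, f3$truth$tip_x))
  # the generator does not disturb the session RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(suppressWarnings(
    make_branching_volume(fixture_spec(seed = 7))))
  expect_identical(runif(1), before)
})

test_that("a single vertical branch is recovered exactly", {
  fx <- make_branching_volume(fixture_spec(n_branches = 1,
                                           elevation_deg = 90, seed = 1))
  sk <- skeletonize(fx$volume)
  tt <- terminal_thickness(sk, fx$volume)
  expect_equal(length(tt$endpoint_nodes), 1L)
  expect_equal(tt$mean_dc, 6e-3, tolerance = 1e-3 / 6e-3)   # 2 x 3 mm
})

test_that("heavily overlapping specs warn with the overlap fraction", {
  sp <- fixture_spec(n_branches = 12, length_range = c(0.015, 0.015),
                     radius_range = c(0.004, 0.004), seed = 1)
  expect_warning(make_branching_volume(sp), "overlap")
})

test_that("fixture volumes are connected with ground truth inside the grid", {
  fx <- suppressWarnings(make_branching_volume(fixture_spec(seed = 4)))
  lab <- coralmorph:::cpp_label_components(fx$volume$mask,
                                           dim(fx$volume$mask), 26L)
  expect_equal(max(lab), 1L)
  # tips lie inside the volume bounds
  lo <- fx$volume$origin
  hi <- lo + dim(fx$volume$mask) * fx$volume$pitch
  expect_true(all(fx$truth$tip_x > lo[1] & fx$truth$tip_x < hi[1]))
  expect_true(all(fx$truth$tip_z < hi[3]))
})

test_that("analytic reference cases expose their closed forms", {
  cases <- analytic_flow_cases()
  expect_named(cases, c("poiseuille", "slab", "absorber"))
  pc <- cases$poiseuille
  expect_equal(pc$exact(pc$H / 2), 1.5 * pc$u0)   # parabolic maximum
  expect_equal(pc$exact(0), 0)
  sc <- cases$slab
  expect_equal(sc$exact(0), 0)
  expect_equal(sc$exact(sc$L), 1)
  expect_equal(sc$U * sc$L / sc$D, 5)              # configured Peclet
  ab <- cases$absorber
  expect_equal(ab$exact(ab$R), 0)
  expect_lt(abs(ab$exact(1e3) - 1), 1e-5)
  expect_gt(ab$exact_shell(2 * ab$R), 0.4)
  expect_true(any(ab$domain$cellcode == 1L))
  expect_true(any(ab$domain$cellcode == 2L))
})
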