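test_that("pure diffusion across a slab gives the linear profile", {
  nx <- 32L
  dom <- simulation_domain(extent = c(0.1, 0.01, 0.01), n = c(nx, 3, 3))
  tp <- transport_params(D = 1e-3,
                         face_concentration = c(1, 0, NA, NA, NA, NA))
  cf <- solve_transport(dom, NULL, tp)
  xc <- (seq_len(nx) - 0.5) / nx
  expect_lt(max(abs(cf$c[, 2, 2] - (1 - xc))), 0.01)
})

test_that("1-D advection-diffusion matches the exponential closed form within 3%", {
  sc <- analytic_flow_cases()$slab
  n <- sc$domain$n
  flow <- structure(list(u = array(sc$U, dim = c(n[1] + 1, n[2], n[3])),
                         v = array(0, dim = c(n[1], n[2] + 1, n[3])),
                         w = array(0, dim = c(n[1], n[2], n[3] + 1)),
                         params = list(u0 = sc$U, tol = 1e-3)),
                    class = "flow_field")
  cf <- solve_transport(sc$domain, flow, sc$transport)
  xc <- (seq_len(n[1]) - 0.5) * sc$domain$pitch[1]
  expect_lt(max(abs(cf$c[, 2, 2] - sc$exact(xc))), 0.03)
  # discrete maximum principle
  expect_gte(min(cf$c), 0)
  expect_lte(max(cf$c), 1)
})

test_that("the maximum principle holds on colony transport solves", {
  dom <- small_channel()
  col <- make_initial_colony(0.06, 0, 0.005, center_xy = c(0.15, 0.15))
  dom <- voxelize_colony(col, dom)
  ff <- solve_flow(dom, fluid_params())
  tp <- transport_params(D = 1e-4)       # advection-dominated
  cf <- solve_transport(dom, ff, tp)
  expect_gte(min(cf$c), 0)
  expect_lte(max(cf$c), tp$cb)
  # upstream-facing polyps absorb more than downstream-facing ones
  fx <- absorbed_flux(col, cf, tp, dom)
  up <- col$normals[, 1] < -0.3
  dn <- col$normals[, 1] > 0.3
  expect_gt(mean(fx[up]), mean(fx[dn]))
  # normalization: the best-fed polyp has flux exactly 1
  expect_equal(max(fx), 1)
  expect_true(all(fx >= 0 & fx <= 1))
})

test_that("absorbed flux is uniform on a free sphere without flow", {
  dom <- simulation_domain(extent = c(0.28, 0.28, 0.28), n = c(56, 56, 56),
                           face_bc = c("inlet", "outlet", "open", "open",
                                       "open", "open"))
  sph <- make_icosphere(3, radius = 0.03)
  sph <- tri_surface(sweep(sph$vertices, 2, rep(0.14, 3), "+"), sph$faces)
  dom <- voxelize_colony(sph, dom)
  # sample two voxels out: at one voxel the staircase of the voxelized
  # sphere contributes ~10% apparent spread that is discretization, not
  # transport physics
  tp <- transport_params(D = 1e-3, l = 1e-2,
                         face_concentration = rep(1, 6))   # no substratum
  cf <- solve_transport(dom, NULL, tp)
  fx <- absorbed_flux(sph, cf, tp, dom)
  expect_lt((max(fx) - min(fx)) / mean(fx), 0.10)
})

test_that("normalized flux is insensitive to the choice of D and l", {
  dom <- simulation_domain(extent = c(0.28, 0.28, 0.28), n = c(56, 56, 56),
                           face_bc = c("inlet", "outlet", "open", "open",
                                       "open", "open"))
  sph <- make_icosphere(3, radius = 0.03)
  sph <- tri_surface(sweep(sph$vertices, 2, rep(0.14, 3), "+"), sph$faces)
  dom <- voxelize_colony(sph, dom)
  # halving D leaves the steady diffusion field unchanged, and doubling the
  # sampling distance must not change the normalized flux (both sampling
  # distances resolve the grid)
  tpA <- transport_params(D = 1e-3, l = 1e-2, face_concentration = rep(1, 6))
  tpB <- transport_params(D = 5e-4, l = 2e-2, face_concentration = rep(1, 6))
  fxA <- absorbed_flux(sph, solve_transport(dom, NULL, tpA), tpA, dom)
  fxB <- absorbed_flux(sph, solve_transport(dom, NULL, tpB), tpB, dom)
  expect_lt(max(abs(fxA - fxB)), 0.05)
})

test_that("a fully screened colony raises the starvation error", {
  dom <- simulation_domain(extent = c(0.1, 0.1, 0.1), n = c(10, 10, 10))
  col <- make_icosphere(2, radius = 0.03)
  col <- tri_surface(sweep(col$vertices, 2, rep(0.05, 3), "+"), col$faces)
  dom <- voxelize_colony(col, dom, clearance = 0L)
  conc <- structure(list(c = array(0, dim = dom$n), sweeps = 0L,
                         params = NULL), class = "conc_field")
  expect_error(absorbed_flux(col, conc, transport_params(D = 1), dom),
               "starvation")
})

test_that("Peclet number worked examples and guards", {
  expect_equal(peclet_number(0.05, 2.26e-3, 1e-4), 1.13)
  expect_equal(peclet_number(0.05, 2.71e-3, 1e-3), 0.1355)
  expect_equal(peclet_number(0, 1e-3, 1e-3), 0)
  expect_error(peclet_number(0.05, 0, 1e-3), "positive")
  expect_error(peclet_number(0.05, 1e-3, 0), "positive")
})
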