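test_that("zero inlet velocity returns the zero field", {
  dom <- simulation_domain(extent = c(0.1, 0.1, 0.1), n = c(8, 8, 8))
  ff <- solve_flow(dom, fluid_params(u0 = 0))
  expect_equal(max(abs(ff$u)), 0)
  expect_equal(max(abs(ff$v)), 0)
  expect_equal(max(abs(ff$w)), 0)
})

test_that("developing channel flow conserves mass past the colony-free bed", {
  # closed duct (free-slip sides, no-slip bed): the substratum boundary
  # layer displaces flux, so the core accelerates above the inlet speed
  dom <- simulation_domain(extent = c(0.24, 0.12, 0.1), n = c(24, 12, 10),
                           face_bc = c("inlet", "outlet", "freeslip",
                                       "freeslip", "noslip", "freeslip"))
  fp <- fluid_params(maxit = 5000L)
  ff <- solve_flow(dom, fp)
  # boundary layer at the substratum: centreline speed at least the inlet
  expect_gte(max(ff$u[20, , ]), fp$u0)
  # discrete continuity everywhere
  dv <- flow_divergence(ff, dom)
  expect_lt(max(abs(dv)) * max(dom$pitch) / fp$u0, fp$tol)
})

test_that("plane Poiseuille flow reproduces the parabolic profile within 3%", {
  pc <- analytic_flow_cases()$poiseuille
  ff <- solve_flow(pc$domain, pc$params)
  n <- pc$domain$n
  zc <- (seq_len(n[3]) - 0.5) * pc$domain$pitch[3]
  prof <- ff$u[round(0.8 * n[1]), 2, ]
  expect_lt(max(abs(prof - pc$exact(zc))) / max(pc$exact(zc)), 0.03)
})

test_that("flow around a colony is laminar, mass-conserving, with a wake deficit", {
  dom <- small_channel()
  col <- make_initial_colony(0.06, 0, 0.005, center_xy = c(0.15, 0.15))
  dom <- voxelize_colony(col, dom)
  fp <- fluid_params()             # Re_colony ~ 100 at mu = 5e-2
  ff <- solve_flow(dom, fp)
  dv <- flow_divergence(ff, dom)
  expect_lt(max(abs(dv)) * max(dom$pitch) / fp$u0, fp$tol)
  # global balance: inflow = outflow through outlet + open faces
  n <- dom$n; h <- dom$pitch
  Ax <- h[2] * h[3]; Ay <- h[1] * h[3]; Az <- h[1] * h[2]
  qin <- sum(ff$u[1, , ]) * Ax
  qout <- sum(ff$u[n[1] + 1, , ]) * Ax +
    sum(ff$v[, n[2] + 1, ]) * Ay - sum(ff$v[, 1, ]) * Ay +
    sum(ff$w[, , n[3] + 1]) * Az
  expect_lt(abs(qout - qin) / qin, 0.005)
  # downstream centreline deficit behind the colony
  expect_gt(fp$u0 - min(ff$u[23, 13:17, 1:5]), 0)
  # warm start after one growth layer converges faster than cold
  col2 <- remesh(accrete(col, rep(5e-4, nrow(col$vertices))), 0.005)
  dom2 <- voxelize_colony(col2, dom)
  warm <- solve_flow(dom2, fp, warm_start = ff)
  cold <- solve_flow(dom2, fp)
  expect_lt(warm$iterations, cold$iterations)
})

test_that("the laminar-regime guard refuses turbulent-wake Reynolds numbers", {
  dom <- small_channel()
  col <- make_initial_colony(0.06, 0, 0.005, center_xy = c(0.15, 0.15))
  dom <- voxelize_colony(col, dom)
  expect_error(solve_flow(dom, fluid_params(mu = 1e-3)), "Reynolds")
})

test_that("colony voxelization is volume-consistent and watertight-checked", {
  dom <- small_channel(n = c(40, 40, 28), extent = c(0.2, 0.2, 0.14))
  # full sphere (no clip): count within 10% of (pi/6) d^3 / h^3
  sph <- make_icosphere(3, radius = 0.03)
  sph$vertices <- sweep(sph$vertices, 2, c(0.1, 0.1, 0.07), "+")
  sph <- tri_surface(sph$vertices, sph$faces)
  dom2 <- voxelize_colony(sph, dom)
  expect_equal(sum(dom2$cellcode == 1L) * prod(dom2$pitch),
               pi / 6 * 0.06^3, tolerance = 0.1)
  # empty surface -> all fluid
  dom3 <- voxelize_colony(NULL, dom)
  expect_equal(sum(dom3$cellcode), 0L)
  # procedural 3-branch solid: voxel volume within 10% of mesh volume is
  # checked on the mesh-voxelizer path via mesh_to_volume
  vol <- mesh_to_volume(sph, 0.0025)
  expect_equal(sum(vol$mask) * prod(vol$pitch),
               surface_area_volume(sph)[["volume"]], tolerance = 0.1)
  # clearance guard
  domx <- simulation_domain(extent = c(0.08, 0.2, 0.14), n = c(16, 40, 28))
  sph2 <- make_icosphere(3, radius = 0.03)
  sph2$vertices <- sweep(sph2$vertices, 2, c(0.04, 0.1, 0.07), "+")
  expect_error(voxelize_colony(tri_surface(sph2$vertices, sph2$faces), domx),
               "clearance|inlet")
})

test_that("Reynolds number worked examples and guard", {
  expect_equal(reynolds_number(1000, 0.05, 0.02, 1e-3), 1000)
  expect_equal(reynolds_number(1000, 0.05, 0.1, 5e-2), 100)
  expect_equal(reynolds_number(1000, 0.15, 1.92e-3, 1e-3), 288)
  expect_error(reynolds_number(1000, 0.05, 0.02, 0), "viscosity")
})
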