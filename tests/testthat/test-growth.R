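test_that("surface diffusion leaves uniform fields unchanged", {
  s <- make_icosphere(3, radius = 0.03)
  st <- surface_diffuse(s, rep(0.7, nrow(s$vertices)), D_s = 3e-4,
                        tau_s = 0.5)
  expect_equal(st$C, rep(0.7, nrow(s$vertices)), tolerance = 1e-10)
})

test_that("long-time surface diffusion relaxes to the area-weighted mean", {
  s <- make_icosphere(3, radius = 0.03)
  set.seed(3)
  fx <- runif(nrow(s$vertices))
  st <- surface_diffuse(s, fx, D_s = 3e-4, tau_s = 500, substeps = 64L)
  target <- sum(fx * st$mass) / sum(st$mass)
  expect_lt(max(abs(st$C - target)), 1e-4)
})

test_that("surface diffusion conserves total nutrient mass on closed surfaces", {
  s <- make_icosphere(3, radius = 0.03)
  set.seed(5)
  fx <- runif(nrow(s$vertices))
  for (tau in c(0.01, 0.5, 10)) {
    st <- surface_diffuse(s, fx, D_s = 3e-4, tau_s = tau)
    m0 <- sum(fx * st$mass)
    expect_lt(abs(sum(st$C * st$mass) - m0) / m0, 1e-6)
  }
})

test_that("implicit surface diffusion matches the explicit fine-step oracle", {
  s <- make_icosphere(2, radius = 0.03)
  # two-patch field: 1 on the upper hemisphere, 0 on the lower
  fx <- as.numeric(s$vertices[, 3] > 0)
  tau <- 0.3
  st <- surface_diffuse(s, fx, D_s = 3e-4, tau_s = tau, substeps = 64L)
  # brute-force explicit Euler with very fine steps on the same Laplacian
  lap <- coralmorph:::cotan_laplacian(s)
  L <- as.matrix(lap$L)
  C <- fx
  nstep <- 8000L
  dt <- tau / nstep
  for (i in seq_len(nstep)) C <- C - dt * 3e-4 * (L %*% C) / lap$mass
  expect_lt(max(abs(st$C - C)), 0.01 * max(abs(C)))
})

test_that("degenerate triangles are reported by the Laplacian", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0), c(0.5, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(3, 2, 4))
  s <- suppressWarnings(tri_surface(v, f))
  expect_error(surface_diffuse(s, rep(1, 4), 3e-4, 1), "degenerate|triangle")
})

test_that("the growth response is a saturating sigmoid with half-max at K", {
  gp <- growth_params()
  expect_equal(growth_response(0, gp), 0)
  expect_equal(growth_response(1, gp), 0.5e-3)       # C = K -> L_max / 2
  # direct evaluation of the Hill form (independent arithmetic)
  expect_equal(growth_response(2, gp),
               1e-3 * 2^1.2 / (1 + 2^1.2), tolerance = 1e-12)
  expect_equal(growth_response(2, gp), 6.967e-4, tolerance = 1e-3)
  # monotone and bounded by L_max
  C <- seq(0, 50, by = 0.1)
  g <- growth_response(C, gp)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < gp$L_max))
  expect_equal(growth_response(1e6, gp), gp$L_max, tolerance = 1e-4)
  expect_error(growth_response(-1, gp), "negative")
})

test_that("the logistic variant shares the endpoints of the Hill form", {
  gp <- growth_params(form = "logistic")
  expect_equal(growth_response(0, gp), 0)
  g <- growth_response(seq(0, 20, by = 0.1), gp)
  expect_true(all(diff(g) > 0))
  expect_true(all(g <= gp$L_max))
})

test_that("growth contrast increases with the kinetic order n", {
  # one diffusion-limited nutrient field mapped through increasingly steep
  # growth curves; contrast is the relative variance of the layer
  # thicknesses against that of the nutrient field (scale-free, since mean
  # growth itself shrinks as n rises while most polyps sit below K)
  s <- make_initial_colony(0.06, 0, 0.005, center_xy = c(0.15, 0.15))
  dom <- small_channel()
  dom <- voxelize_colony(s, dom)
  cf <- solve_transport(dom, NULL, transport_params(D = 1.0))
  fx <- absorbed_flux(s, cf, transport_params(D = 1.0), dom)
  st <- surface_diffuse(s, fx, 3e-4, 0.2)
  cv2 <- function(x) (sd(x) / mean(x))^2
  keep <- !s$boundary                      # rim polyps never grow
  contrast <- vapply(c(1.0, 1.4, 2.2, 2.4, 2.6), function(n) {
    l <- growth_response(st$C[keep], growth_params(n = n))
    cv2(l) / cv2(st$C[keep])
  }, 0)
  expect_true(all(diff(contrast) > 0))
})

test_that("a zero-step run returns the initial colony unchanged", {
  dom <- small_channel()
  col <- make_initial_colony(0.06, 0, 0.005, center_xy = c(0.15, 0.15))
  run <- grow_colony(colony = col, domain = dom,
                     growth = growth_params(steps = 0L, target_edge = 5e-3),
                     flow = FALSE)
  expect_equal(run$final$vertices, col$vertices)
  expect_null(run$stats)
  expect_equal(colony_extension_check(run$final), 0.06, tolerance = 0.02)
})

test_that("uniform saturated nutrient extends the colony by L_max/2 per step", {
  # direct accretion check: C = K everywhere -> every free vertex advances
  # 0.5 mm along its normal, so the colony top rises 0.5 mm per step
  col <- make_initial_colony(0.06, 0, 0.005)
  gp <- growth_params(target_edge = 5e-3)
  ztop <- max(col$vertices[, 3])
  for (step in 1:3) {
    l <- growth_response(rep(gp$K, nrow(col$vertices)), gp)
    col <- accrete(col, l)
    expect_equal(max(col$vertices[, 3]), ztop + step * 0.5e-3,
                 tolerance = 1e-6)
  }
})

test_that("diffusion-limited growth amplifies flux contrast and extends monotonically", {
  dom <- small_channel()
  run <- grow_colony(domain = dom, fluid = fluid_params(u0 = 0), flow = FALSE,
                     transport = transport_params(D = 1.0),
                     growth = growth_params(steps = 8L, target_edge = 5e-3))
  expect_true(all(diff(run$stats$extent) > 0))
  expect_true(all(diff(run$stats$volume) > 0))
  # instability amplification: flux spread grows over the early steps
  expect_gt(max(run$stats$flux_cv), run$stats$flux_cv[1])
})

test_that("growth runs are deterministic", {
  dom <- small_channel()
  g <- growth_params(steps = 2L, target_edge = 5e-3)
  r1 <- grow_colony(domain = dom, transport = transport_params(D = 1e-3),
                    growth = g, keep_history = FALSE)
  r2 <- grow_colony(domain = dom, transport = transport_params(D = 1e-3),
                    growth = g, keep_history = FALSE)
  expect_identical(r1$final$vertices, r2$final$vertices)
})
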