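#' Fluid parameters
#'
#' Physical and solver parameters for the steady laminar flow solve.  The
#' defaults are the simulation settings used throughout: sea-water density,
#' a dynamic viscosity raised to 5e-2 Pa s so that turbulence is suppressed
#' by viscous forces (colony Reynolds number ~100), a 0.05 m/s uniform inlet
#' velocity, and a relative iterative-solver tolerance of 1e-3.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param rho fluid density (kg m^-3).
#' @param u0 uniform inlet speed (m s^-1).
#' @param tol relative residual tolerance for momentum and continuity.
#' @param maxit maximum outer (SIMPLE) iterations.
#' @param alpha_u,alpha_p velocity / pressure under-relaxation factors.
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(mu = 5e-2, rho = 1000, u0 = 0.05, tol = 1e-3,
                         maxit = 3000L, alpha_u = 0.7, alpha_p = 0.3) {
  stopifnot(mu > 0, rho > 0, u0 >= 0, tol > 0)
  structure(list(mu = mu, rho = rho, u0 = u0, tol = tol,
                 maxit = as.integer(maxit),
                 alpha_u = alpha_u, alpha_p = alpha_p),
            class = "fluid_params")
}

#' Reynolds number
#'
#' `Re = rho * u * L / mu`, the ratio of inertial to viscous forces.  The
#' wake behind a cylinder-like branch stays steady and laminar below
#' `Re ~ 40`, sheds periodically for `40 < Re < 200`, and becomes unstable
#' above.
#'
#' @param rho fluid density (kg m^-3).
#' @param u_mean mean flow speed (m s^-1).
#' @param L characteristic length (m), e.g. branch diameter or colony extent.
#' @param mu dynamic viscosity (Pa s).
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, u_mean, L, mu) {
  if (any(mu <= 0)) stop("dynamic viscosity must be positive")
  rho * u_mean * L / mu
}

face_bc_codes <- function(face_bc) {
  match(face_bc, c("inlet", "outlet", "open", "noslip", "freeslip")) - 1L
}

colony_extent <- function(domain) {
  if (!any(domain$cellcode == 1L)) return(NA_real_)
  idx <- which(domain$cellcode == 1L, arr.ind = TRUE)
  max((apply(idx, 2, function(x) diff(range(x))) + 1) * domain$pitch)
}

#' Solve steady laminar incompressible flow
#'
#' Solves the steady incompressible Navier-Stokes and continuity equations
#' (no external volume force) in the channel around the voxelized colony with
#' a staggered finite-volume SIMPLE iteration: no-slip on the substratum and
#' colony surface, uniform inlet velocity, zero pressure and viscous stress at
#' the outlet, and open lateral/top boundaries.  Warm starting from a previous
#' step's field is supported and makes successive solves on slowly growing
#' geometry converge much faster.
#'
#' @param domain a [simulation_domain()], typically after [voxelize_colony()].
#' @param params a [fluid_params()].
#' @param warm_start optional `flow_field` from a previous solve on the same
#'   grid.
#' @param re_max laminar-regime guard: refuse colony Reynolds numbers above
#'   this value (default 200, the onset of unsteady wakes).
#' @return object of class `flow_field` with staggered face velocities `u`,
#'   `v`, `w`, cell pressures `p`, and residual history.
#' @export
solve_flow <- function(domain, params = fluid_params(), warm_start = NULL,
                       re_max = 200) {
  stopifnot(inherits(domain, "sim_domain"), inherits(params, "fluid_params"))
  L <- colony_extent(domain)
  if (!is.na(L)) {
    re <- reynolds_number(params$rho, params$u0, L, params$mu)
    if (re > re_max)
      stop(sprintf(paste0("colony Reynolds number %.3g exceeds the steady ",
                          "laminar limit %.3g; raise viscosity to suppress ",
                          "turbulence"), re, re_max))
  }
  empty <- numeric(0)
  ws <- function(comp) if (is.null(warm_start)) empty else warm_start[[comp]]
  res <- cpp_solve_flow(domain$cellcode, domain$n, domain$pitch,
                        face_bc_codes(domain$face_bc),
                        params$mu, params$rho, params$u0, params$tol,
                        params$maxit, params$alpha_u, params$alpha_p,
                        ws("u"), ws("v"), ws("w"), ws("p"))
  if (!res$converged) {
    stop(sprintf(paste0("flow solver did not converge in %d iterations ",
                        "(momentum residual %.3g, continuity %.3g)"),
                 res$iterations, utils::tail(res$res_mom, 1),
                 utils::tail(res$res_mass, 1)))
  }
  structure(c(res, list(params = params)), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %s cells, %d iterations, max |u| = %.3g m/s\n",
              paste(dim(x$p), collapse = "x"), x$iterations, max(abs(x$u))))
  invisible(x)
}

#' Discrete divergence of a flow field
#'
#' Per-cell velocity divergence (s^-1) of the staggered field; the continuity
#' invariant requires `max |div u| * h / u0` at or below the solver tolerance.
#'
#' @param flow a `flow_field`.
#' @param domain the [simulation_domain()] it was solved on.
#' @return array of per-cell divergence values.
#' @export
flow_divergence <- function(flow, domain) {
  n <- domain$n; h <- domain$pitch
  u <- flow$u; v <- flow$v; w <- flow$w
  du <- (u[2:(n[1] + 1), , , drop = FALSE] - u[1:n[1], , , drop = FALSE]) / h[1]
  dv <- (v[, 2:(n[2] + 1), , drop = FALSE] - v[, 1:n[2], , drop = FALSE]) / h[2]
  dw <- (w[, , 2:(n[3] + 1), drop = FALSE] - w[, , 1:n[3], drop = FALSE]) / h[3]
  out <- du + dv + dw
  out[domain$cellcode == 1L] <- 0
  array(out, dim = n)
}

# cell-centred speed, for slice rendering and mean-velocity summaries
cell_speed <- function(flow, domain) {
  n <- domain$n
  uc <- (flow$u[1:n[1], , , drop = FALSE] + flow$u[2:(n[1] + 1), , , drop = FALSE]) / 2
  vc <- (flow$v[, 1:n[2], , drop = FALSE] + flow$v[, 2:(n[2] + 1), , drop = FALSE]) / 2
  wc <- (flow$w[, , 1:n[3], drop = FALSE] + flow$w[, , 2:(n[3] + 1), drop = FALSE]) / 2
  array(sqrt(uc^2 + vc^2 + wc^2), dim = n)
}
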