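#' Nutrient transport parameters
#'
#' Parameters of the steady advection-diffusion solve.  Nutrient enters with
#' the idealized boundary concentration 1 mol m^-3 on every domain face
#' except the substratum and the colony surface, which absorb it completely
#' (c = 0).  The absorbed flux read off at a small distance `l` along each
#' vertex normal is normalized by its maximum, which makes it independent of
#' the choice of `D` and `l`.
#'
#' @param D diffusion coefficient (m^2 s^-1).  The Peclet sweep lowers this
#'   by factors of 10 from 1.0 to 1.0e-5 while keeping the velocity fixed.
#' @param cb far-field boundary concentration (mol m^-3), default 1.0.
#' @param l sampling distance along the vertex normal (m); default one voxel
#'   pitch, chosen at solve time when `NULL`.
#' @param tol relative residual stopping criterion (default 1e-6).
#' @param maxsweep maximum SOR sweeps.
#' @param omega SOR over-relaxation factor; `NULL` picks 1.85 for pure
#'   diffusion and 1.4 when advection is present.
#' @param face_concentration optional length-6 override of the Dirichlet
#'   concentrations on faces `x-`, `x+`, `y-`, `y+`, `z-`, `z+`; `NA` entries
#'   mean a zero-gradient (no-flux) face.  Default: `cb` everywhere except 0
#'   on the substratum (`z-`).
#' @return object of class `transport_params`.
#' @export
transport_params <- function(D, cb = 1.0, l = NULL, tol = 1e-6,
                             maxsweep = 50000L, omega = NULL,
                             face_concentration = NULL) {
  stopifnot(D > 0, cb > 0, is.null(l) || l > 0, tol > 0)
  structure(list(D = D, cb = cb, l = l, tol = tol,
                 maxsweep = as.integer(maxsweep), omega = omega,
                 face_concentration = face_concentration),
            class = "transport_params")
}

#' Solve steady nutrient advection-diffusion
#'
#' Solves `u . grad c = D laplacian c` on the flow solution with first-order
#' upwind convection (monotone, so `0 <= c <= cb` holds everywhere) and
#' Dirichlet boundaries: `cb` on the far-field faces, 0 on the colony and the
#' substratum.
#'
#' @param domain a [simulation_domain()] with the colony voxelized.
#' @param flow a `flow_field` from [solve_flow()], or `NULL` for the no-flow
#'   (pure diffusion) limit.
#' @param params a [transport_params()].
#' @param warm_start optional previous `conc_field` on the same grid.
#' @return object of class `conc_field` with the cell-centred concentration
#'   array `c` (mol m^-3).
#' @export
solve_transport <- function(domain, flow, params, warm_start = NULL) {
  stopifnot(inherits(domain, "sim_domain"), inherits(params, "transport_params"))
  facec <- params$face_concentration %||%
    c(params$cb, params$cb, params$cb, params$cb, 0, params$cb)
  stopifnot(length(facec) == 6)
  if (is.null(flow)) {
    u <- v <- w <- numeric(1)
  } else {
    dv <- flow_divergence(flow, domain)
    h <- max(domain$pitch)
    u0 <- max(abs(flow$params$u0), 1e-12)
    if (max(abs(dv)) * h / u0 > 10 * flow$params$tol)
      stop("flow field violates the continuity invariant; re-solve flow first")
    u <- flow$u; v <- flow$v; w <- flow$w
  }
  omega <- params$omega %||% (if (is.null(flow)) 1.85 else 1.4)
  init <- if (is.null(warm_start)) numeric(0) else warm_start$c
  res <- cpp_solve_transport(domain$cellcode, domain$n, domain$pitch,
                             u, v, w, params$D, params$cb, as.numeric(facec),
                             params$tol, params$maxsweep, omega, init)
  if (!res$converged)
    stop(sprintf("transport solver did not converge in %d sweeps (relative residual %.3g)",
                 res$sweeps, utils::tail(res$residual, 1)))
  structure(list(c = res$c, sweeps = res$sweeps, params = params,
                 residual = res$residual), class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("<conc_field> %s cells, %d sweeps, c in [%.3g, %.3g] mol/m^3\n",
              paste(dim(x$c), collapse = "x"), x$sweeps, min(x$c), max(x$c)))
  invisible(x)
}

#' Per-vertex normalized absorbed flux
#'
#' Interpolates the nutrient concentration a small distance `l` along each
#' vertex normal and normalizes by the maximum sampled concentration
#' `c_max`, so the flux lies in `[0, 1]` with a maximum of exactly 1.
#' Because the surface concentration is zero, this normalized near-surface
#' concentration is proportional to the absorbed diffusive flux and
#' independent of `D` and `l` for a thin boundary layer.
#'
#' @param surface a [tri_surface()].
#' @param conc a `conc_field` from [solve_transport()].
#' @param params the [transport_params()] used (provides `l`).
#' @param domain the [simulation_domain()] of the solve.
#' @return numeric vector of per-vertex flux values in `[0, 1]`.
#' @export
absorbed_flux <- function(surface, conc, params, domain) {
  stopifnot(inherits(surface, "tri_surface"), inherits(conc, "conc_field"))
  l <- params$l %||% max(domain$pitch)
  pts <- surface$vertices + l * surface$normals
  samp <- cpp_trilinear(conc$c, domain$n, domain$origin, domain$pitch, pts)
  cmax <- max(samp)
  if (cmax <= 0)
    stop("colony is fully screened from nutrient (c_max = 0): starvation state")
  pmin(pmax(samp / cmax, 0), 1)
}

#' Peclet number
#'
#' `Pe = u * L / D`, the ratio of advective to diffusive nutrient transport.
#' Without fluid motion diffusion dominates and `Pe` is low; large `Pe`
#' marks the advection-dominated regime.  The characteristic length used for
#' colonies is the mean terminal-branch diameter `dc`.
#'
#' @param u_mean mean flow speed (m s^-1).
#' @param L characteristic length (m).
#' @param D diffusion coefficient (m^2 s^-1).
#' @return dimensionless Peclet number.
#' @export
peclet_number <- function(u_mean, L, D) {
  if (any(D <= 0) || any(L <= 0))
    stop("characteristic length and diffusion coefficient must be positive")
  u_mean * L / D
}
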