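#' Growth parameters
#'
#' Parameters of the accretive growth step.  `L_max` is the asymptotic
#' maximum extension per growth step (1 mm), `K` the half-saturation
#' concentration (1 mol m^-3, the normalization of absorbed flux), `n` the
#' kinetic order of the growth response (1.2, a slightly steeper sigmoid),
#' and `D_s` the surface diffusion coefficient (3e-4 m^2 s^-1, an
#' intermediate branching regime).  Because absorbed flux is normalized to a
#' maximum of 1 = `K`, the best-fed polyp extends about half a millimetre
#' per step; 150 steps grow the 6 cm seed to roughly 10 cm, comparable to
#' 1-2 cm/year colonies.
#'
#' @param L_max asymptotic maximum layer thickness (m).
#' @param K half-saturation concentration (mol m^-3).
#' @param n kinetic order (>= 1) of the growth response.
#' @param D_s surface diffusion coefficient (m^2 s^-1).
#' @param tau_s surface-diffusion integration time per growth step (s);
#'   default gives a lateral translocation length `sqrt(D_s tau_s)` of three
#'   remesh target edges, which sets the branch spacing.
#' @param steps number of growth steps (default 40, a desk-scale run; 150
#'   reaches the full ~10 cm colony).
#' @param target_edge remesh target edge length (m).
#' @param form growth-response shape: `"hill"` (default) or `"logistic"`.
#' @param substeps implicit integration substeps for surface diffusion.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(L_max = 1e-3, K = 1.0, n = 1.2, D_s = 3e-4,
                          tau_s = NULL, steps = 40L, target_edge = 4e-3,
                          form = c("hill", "logistic"), substeps = 16L) {
  stopifnot(L_max > 0, K > 0, D_s > 0, n >= 1, target_edge > 0,
            is.null(tau_s) || tau_s > 0)
  form <- match.arg(form)
  if (is.null(tau_s)) tau_s <- (3 * target_edge)^2 / D_s
  structure(list(L_max = L_max, K = K, n = n, D_s = D_s, tau_s = tau_s,
                 steps = as.integer(steps), target_edge = target_edge,
                 form = form, substeps = as.integer(substeps)),
            class = "growth_params")
}

# cotangent-weighted graph Laplacian (positive semi-definite, L 1 = 0) and
# lumped vertex areas (one third of incident triangle area per vertex)
cotan_laplacian <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  n <- nrow(v)
  areas <- triangle_areas(v, f)
  if (any(!is.finite(areas)) || any(areas < 1e-18))
    stop("degenerate triangle in surface-diffusion Laplacian: triangle ",
         which(!is.finite(areas) | areas < 1e-18)[1])
  cot_at <- function(p, q, r) {             # cotangent of angle at p
    e1 <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    e2 <- v[r, , drop = FALSE] - v[p, , drop = FALSE]
    dotp <- rowSums(e1 * e2)
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    crs <- sqrt(cx^2 + cy^2 + cz^2)
    out <- dotp / pmax(crs, 1e-300)
    if (any(!is.finite(out)))
      stop("non-finite cotangent weight at triangle ",
           which(!is.finite(out))[1])
    out
  }
  # edge (q, r) opposite vertex p carries weight cot(p) / 2
  i <- c(f[, 2], f[, 3], f[, 1])
  j <- c(f[, 3], f[, 1], f[, 2])
  w <- c(cot_at(f[, 1], f[, 2], f[, 3]),
         cot_at(f[, 2], f[, 3], f[, 1]),
         cot_at(f[, 3], f[, 1], f[, 2])) / 2
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  va <- numeric(n)
  for (corner in 1:3) {
    acc <- rowsum(areas, f[, corner])
    va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc / 3
  }
  list(L = L, mass = va)
}

#' Surface diffusion of absorbed nutrient
#'
#' Translocates absorbed nutrient between neighbouring polyps by solving the
#' heat equation `dC/dt = D_s lap_s C` on the colony surface for time
#' `tau_s`, starting from the absorbed-flux field.  The mesh Laplacian uses
#' cotangent weights with lumped vertex areas, integrated by a
#' Crank-Nicolson scheme; on closed surfaces total area-weighted nutrient
#' mass is conserved to near machine precision.
#'
#' @param surface a [tri_surface()].
#' @param flux per-vertex absorbed flux (non-negative, length = vertex count).
#' @param D_s surface diffusion coefficient (m^2 s^-1).
#' @param tau_s integration time (s).
#' @param substeps number of implicit substeps.
#' @return object of class `polyp_state`: list with `flux` (input) and `C`
#'   (translocated concentration, mol m^-3).
#' @export
surface_diffuse <- function(surface, flux, D_s, tau_s, substeps = 16L) {
  n <- nrow(surface$vertices)
  if (length(flux) != n) stop("flux must match vertex count")
  if (any(flux < 0)) stop("negative absorbed flux")
  lap <- cotan_laplacian(surface)
  dt <- tau_s / substeps
  M <- Matrix::Diagonal(n, lap$mass)
  # Crank-Nicolson substeps for accuracy, closed by two backward-Euler
  # substeps that damp the stiff-mode ringing CN leaves on long horizons
  A <- M + (0.5 * dt * D_s) * lap$L
  B <- M - (0.5 * dt * D_s) * lap$L
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  Abe <- M + (dt * D_s) * lap$L
  fac_be <- Matrix::Cholesky(Matrix::forceSymmetric(Abe), LDL = FALSE)
  nbe <- min(2L, substeps)
  C <- flux
  for (s in seq_len(substeps - nbe)) {
    C <- as.numeric(Matrix::solve(fac, B %*% C))
  }
  for (s in seq_len(nbe)) {
    C <- as.numeric(Matrix::solve(fac_be, M %*% C))
  }
  structure(list(flux = flux, C = C, mass = lap$mass), class = "polyp_state")
}

#' Sigmoidal growth response
#'
#' Converts the translocated nutrient concentration at a polyp into the
#' thickness of the new skeletal layer.  The default saturation-kinetics
#' (Hill) form is `g(C) = L_max C^n / (K^n + C^n)`: zero at zero nutrient,
#' half-maximal at `C = K`, saturating at `L_max` for high uptake.  A
#' normalized logistic alternative with the same endpoints is available.
#'
#' @param C concentration values (mol m^-3), all non-negative.
#' @param params a [growth_params()].
#' @return extension lengths (m), same length as `C`.
#' @export
growth_response <- function(C, params = growth_params()) {
  if (any(C < 0)) stop("negative concentration")
  with(params, {
    if (form == "hill") {
      L_max * C^n / (K^n + C^n)
    } else {
      s <- function(x) 1 / (1 + exp(-n * (x - K) / K))
      L_max * (s(C) - s(0)) / (1 - s(0))
    }
  })
}

#' Run the coupled flow-transport-growth simulation
#'
#' The outer accretive growth loop: each step voxelizes the colony into the
#' channel, solves steady flow (warm-started from the previous step) and
#' nutrient transport, samples the normalized absorbed flux at each polyp,
#' translocates it by surface diffusion, converts it to a growth layer with
#' the sigmoidal response, displaces the surface along its normals, and
#' remeshes.  With `flow = FALSE` (or inlet speed 0) the run is purely
#' diffusion-limited.  The run is deterministic: there is no stochastic
#' term, and any symmetry breaking originates in mesh discreteness.
#'
#' @param colony initial [tri_surface()], or `NULL` to build one from
#'   `colony_args`.
#' @param domain a [simulation_domain()].
#' @param fluid a [fluid_params()].
#' @param transport a [transport_params()].
#' @param growth a [growth_params()].
#' @param flow logical; solve the flow field (otherwise pure diffusion).
#' @param colony_args arguments for [make_initial_colony()] when `colony`
#'   is `NULL`.
#' @param keep_history keep every intermediate surface (else final only).
#' @param verbose print per-step progress.
#' @return object of class `growth_run`: list with `final` surface,
#'   `history` (list of surfaces), `stats` (per-step data frame), `flow`,
#'   `conc` (final fields), and `halted` (self-intersection report or NULL).
#' @export
grow_colony <- function(colony = NULL,
                        domain = simulation_domain(),
                        fluid = fluid_params(),
                        transport = transport_params(D = 1e-3),
                        growth = growth_params(),
                        flow = fluid$u0 > 0,
                        colony_args = list(),
                        keep_history = TRUE,
                        verbose = FALSE) {
  if (is.null(colony)) {
    ca <- modifyList(list(diameter = 0.06,
                          target_edge = growth$target_edge,
                          center_xy = c(domain$extent[1] / 2,
                                        domain$extent[2] / 2)),
                     colony_args)
    colony <- do.call(make_initial_colony, ca)
  }
  surface <- colony
  history <- if (keep_history) list(surface) else list()
  stats <- list()
  ff <- NULL; cf <- NULL; halted <- NULL
  for (step in seq_len(growth$steps)) {
    dom <- voxelize_colony(surface, domain)
    ff <- if (flow) solve_flow(dom, fluid, warm_start = ff) else NULL
    cf <- solve_transport(dom, ff, transport, warm_start = cf)
    fx <- absorbed_flux(surface, cf, transport, dom)
    st <- surface_diffuse(surface, fx, growth$D_s, growth$tau_s,
                          growth$substeps)
    li <- growth_response(st$C, growth)
    grown <- accrete(surface, li, check_intersection = TRUE)
    # the substratum is impenetrable: vertices whose outward normal dips
    # below the plane are clamped to it
    zsub <- domain$origin[3]
    if (any(grown$vertices[, 3] < zsub)) {
      v <- grown$vertices
      v[, 3] <- pmax(v[, 3], zsub)
      grown2 <- tri_surface(v, grown$faces, boundary = grown$boundary,
                            channels = grown$channels)
      attr(grown2, "self_intersections") <- attr(grown, "self_intersections")
      grown <- grown2
    }
    hits <- attr(grown, "self_intersections")
    if (!is.null(hits) && nrow(hits) > 0) {
      halted <- list(step = step, intersections = hits)
      warning(sprintf(paste0("self-intersection (%d triangle pairs) at step ",
                             "%d: branches would fuse; halting"),
                      nrow(hits), step))
      break
    }
    surface <- remesh(grown, growth$target_edge)
    av <- surface_area_volume(surface)
    stats[[step]] <- data.frame(
      step = step, n_vertices = nrow(surface$vertices),
      area = av[["area"]], volume = av[["volume"]],
      sv_ratio = av[["sv_ratio"]],
      extent = colony_extension_check(surface),
      flux_mean = mean(fx), flux_cv = sd(fx) / max(mean(fx), 1e-300),
      layer_mean = mean(li), layer_max = max(li),
      flow_iterations = if (flow) ff$iterations else NA_integer_,
      transport_sweeps = cf$sweeps)
    if (keep_history) history[[step + 1]] <- surface
    if (verbose)
      message(sprintf("step %3d: V=%.3g m^3, S/V=%.0f, extent=%.3f m",
                      step, av[["volume"]], av[["sv_ratio"]],
                      stats[[step]]$extent))
  }
  structure(list(final = surface, history = history,
                 stats = do.call(rbind, stats), flow_field = ff,
                 conc_field = cf, halted = halted,
                 config = list(fluid = fluid, transport = transport,
                               growth = growth, domain = domain[c("extent", "n", "face_bc", "origin")],
                               flow = flow)),
            class = "growth_run")
}

#' @export
print.growth_run <- function(x, ...) {
  ns <- if (is.null(x$stats)) 0L else nrow(x$stats)
  cat(sprintf("<growth_run> %d steps, final %d vertices\n", ns,
              nrow(x$final$vertices)))
  if (ns > 0)
    cat(sprintf("  extent %.3f m, S/V %.0f m^-1\n",
                x$stats$extent[ns], x$stats$sv_ratio[ns]))
  if (!is.null(x$halted))
    cat(sprintf("  halted by self-intersection at step %d\n", x$halted$step))
  invisible(x)
}
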