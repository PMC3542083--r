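#' Procedural branching-colony fixtures
#'
#' Generator specification for synthetic branching solids that emulate
#' CT-scanned colonies at known ground truth, so every morphometric
#' operator can be validated without scan data.  Branches are capsules
#' (sphere-swept segments, so unions stay smooth and skeleton junctions are
#' well defined) radiating from a basal node on a small substratum
#' pedestal.
#'
#' @param n_branches number of branches.
#' @param length_range branch length range (m), sampled uniformly.
#' @param radius_range branch radius range (m), sampled uniformly.
#' @param elevation_deg branch elevation above the horizontal (degrees);
#'   scalar (constant) or length-2 range.
#' @param bias orientation bias in `[0, 1]` of branch azimuths toward
#'   `bias_azimuth_deg`: 0 is isotropic, 1 fully aligned.
#' @param bias_azimuth_deg azimuth (degrees, from +x toward +y) the bias
#'   pulls toward; e.g. 180 biases branches toward -x (upstream).
#' @param pitch output voxel pitch (m), scalar or length 3.
#' @param seed RNG seed; the same seed reproduces the volume bit-exactly.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_branches = 8L, length_range = c(0.04, 0.04),
                         radius_range = c(0.003, 0.003),
                         elevation_deg = 45, bias = 0,
                         bias_azimuth_deg = 180, pitch = 1e-3,
                         seed = 1L) {
  if (length(pitch) == 1) pitch <- rep(pitch, 3)
  stopifnot(n_branches >= 1, bias >= 0, bias <= 1,
            min(radius_range) > 2 * max(pitch))
  structure(list(n_branches = as.integer(n_branches),
                 length_range = length_range, radius_range = radius_range,
                 elevation_deg = elevation_deg, bias = bias,
                 bias_azimuth_deg = bias_azimuth_deg,
                 pitch = pitch, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a branching voxel volume with ground truth
#'
#' Draws branch orientations, lengths and radii from the specification (seeded, so
#' byte-reproducible), rasterizes the union of capsules plus a two-voxel
#' substratum pedestal, and returns the volume together with the ground
#' truth needed by oracle tests: per-branch tip positions, radii and
#' orientations.  A warning reports the overlap fraction when branches
#' merge substantially.
#'
#' @param spec a [fixture_spec()].
#' @return list with `volume` (a [voxel_volume()]) and `truth` (data frame
#'   of branch geometry plus the basal point as attribute `base`).
#' @export
make_branching_volume <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  nb <- spec$n_branches
  len <- runif(nb, spec$length_range[1], spec$length_range[2])
  # a radius per branch may be given explicitly (length n_branches),
  # otherwise radii are drawn uniformly from the range
  rad <- if (length(spec$radius_range) == nb && nb > 2)
    spec$radius_range else runif(nb, min(spec$radius_range),
                                 max(spec$radius_range))
  elev <- if (length(spec$elevation_deg) == 1) rep(spec$elevation_deg, nb)
          else runif(nb, spec$elevation_deg[1], spec$elevation_deg[2])
  az0 <- spec$bias_azimuth_deg * pi / 180
  # azimuths: evenly spaced fan (exactly isotropic at bias 0, so paired
  # projections cancel) with a random global phase, pulled toward the bias
  # azimuth by the bias factor
  phase <- runif(1, 0, 2 * pi)
  base <- phase + 2 * pi * (seq_len(nb) - 1) / nb
  off <- ((base - az0 + pi) %% (2 * pi)) - pi
  az <- az0 + (1 - spec$bias) * off
  if (nb == 1 && length(spec$elevation_deg) == 1 &&
      spec$elevation_deg >= 89) az <- 0   # single vertical branch
  dirs <- cbind(cos(az) * cos(elev * pi / 180),
                sin(az) * cos(elev * pi / 180),
                sin(elev * pi / 180))
  h <- spec$pitch
  rmax <- max(rad)
  base_z <- h[3] / 2                       # basal node on the substratum
  base <- c(0, 0, base_z)
  tips <- sweep(dirs * len, 2, base, "+")
  # grid bounds
  lo <- pmin(apply(tips, 2, min), base) - rmax - 3 * h
  hi <- pmax(apply(tips, 2, max), base) + rmax + 3 * h
  lo[3] <- 0
  n <- as.integer(ceiling((hi - lo) / h))
  # voxel centre coordinates
  xs <- lo[1] + (seq_len(n[1]) - 0.5) * h[1]
  ys <- lo[2] + (seq_len(n[2]) - 0.5) * h[2]
  zs <- lo[3] + (seq_len(n[3]) - 0.5) * h[3]
  mask <- array(FALSE, dim = n)
  claim <- array(0L, dim = n)
  X <- array(rep(xs, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)
  for (b in seq_len(nb)) {
    # distance from voxel centres to segment base -> tip
    vx <- X - base[1]; vy <- Y - base[2]; vz <- Z - base[3]
    t <- (vx * dirs[b, 1] + vy * dirs[b, 2] + vz * dirs[b, 3])
    t <- pmin(pmax(t, 0), len[b])
    dx <- vx - t * dirs[b, 1]; dy <- vy - t * dirs[b, 2]; dz <- vz - t * dirs[b, 3]
    inb <- (dx^2 + dy^2 + dz^2) <= rad[b]^2
    claim <- claim + inb
    mask <- mask | inb
  }
  # substratum pedestal: 2-voxel-thick disk under the basal node (kept
  # barely wider than the thickest branch so its own skeleton collapses)
  ped_r <- 1.05 * rmax
  ped <- (X - base[1])^2 + (Y - base[2])^2 <= ped_r^2 & Z <= 2 * h[3]
  mask <- mask | ped
  overlap <- sum(claim > 1L) / max(sum(claim >= 1L), 1L)
  if (overlap > 0.3)
    warning(sprintf("branches overlap substantially (fraction %.2f): fixture may merge into a blob",
                    overlap))
  vol <- voxel_volume(mask, h, lo)
  truth <- data.frame(branch = seq_len(nb), length = len, radius = rad,
                      elevation_deg = elev,
                      azimuth_deg = (az * 180 / pi) %% 360,
                      tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3])
  attr(truth, "base") <- base
  attr(truth, "overlap_fraction") <- overlap
  list(volume = vol, truth = truth)
}

#' Analytic reference problems for the flow and transport solvers
#'
#' Configured cases with closed-form solutions: plane Poiseuille flow
#' (parabolic profile between no-slip plates), the 1-D
#' advection-diffusion slab (exponential profile), and the spherical
#' absorber in a concentric far-field shell (`1 - R/r` profile).  Each
#' entry carries the domain/parameter setup and a callable exact solution.
#'
#' @return named list of cases (`poiseuille`, `slab`, `absorber`).
#' @export
analytic_flow_cases <- function() {
  poise <- local({
    H <- 0.04; L <- 0.16; u0 <- 0.05; mu <- 0.4; rho <- 1000
    domain <- simulation_domain(extent = c(L, 3 * H / 48, H),
                                n = c(64, 3, 48),
                                face_bc = c("inlet", "outlet", "freeslip",
                                            "freeslip", "noslip", "noslip"))
    list(domain = domain,
         params = fluid_params(mu = mu, rho = rho, u0 = u0, tol = 1e-4,
                               maxit = 20000L),
         exact = function(z) 6 * u0 * (z / H) * (1 - z / H),
         H = H, u0 = u0,
         note = "fully developed profile u(z) = 6 u0 (z/H)(1-z/H)")
  })
  slab <- local({
    L <- 0.1; D <- 1e-3; U <- 5 * D / L    # Pe = UL/D = 5
    nx <- 64L
    domain <- simulation_domain(extent = c(L, 3 * L / nx, 3 * L / nx),
                                n = c(nx, 3, 3))
    tp <- transport_params(D = D, face_concentration = c(0, 1, NA, NA, NA, NA))
    list(domain = domain, transport = tp, U = U, L = L, D = D,
         exact = function(x) (exp(U * x / D) - 1) / (exp(U * L / D) - 1),
         note = "1-D advection-diffusion: c(x) = (e^{Ux/D}-1)/(e^{UL/D}-1)")
  })
  absorber <- local({
    R <- 5; Rout <- 16 * R                 # in voxel units
    h <- 1e-3
    n <- as.integer(2 * Rout + 6)
    domain <- simulation_domain(extent = rep(n * h, 3), n = rep(n, 3))
    cen <- rep(n * h / 2, 3)
    ii <- (seq_len(n) - 0.5) * h
    dist2 <- outer(outer((ii - cen[1])^2, (ii - cen[2])^2, "+"),
                   (ii - cen[3])^2, "+")
    code <- array(0L, dim = rep(n, 3))
    code[dist2 <= (R * h)^2] <- 1L         # absorber (c = 0)
    code[dist2 >= (Rout * h)^2] <- 2L      # far-field shell (c = cb)
    domain$cellcode <- code
    r_eff <- (3 * sum(code == 1L) * h^3 / (4 * pi))^(1 / 3)
    list(domain = domain,
         transport = transport_params(D = 1e-3,
                                      face_concentration = rep(NA, 6)),
         center = cen, R = R * h, Rout = Rout * h, r_eff = r_eff,
         exact = function(r) pmax(1 - (R * h) / r, 0),
         exact_shell = function(r)
           pmax((1 - r_eff / r) / (1 - r_eff / (Rout * h)), 0),
         note = "spherical absorber: c = 1 - R/r (shell-corrected form exact)")
  })
  list(poiseuille = poise, slab = slab, absorber = absorber)
}
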