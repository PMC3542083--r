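#' Terminal-branch thickness
#'
#' At every skeleton endpoint, the diameter `dc` of the largest sphere
#' inscribed in the branch: twice the Euclidean distance-transform value at
#' the endpoint voxel.  The mean `dc` is the characteristic length used in
#' the branch-scale Peclet and Reynolds numbers.  Endpoints whose inscribed
#' sphere touches the volume border are flagged and excluded from the mean.
#'
#' @param skeleton a `skeleton_graph` from [skeletonize()].
#' @param volume the [voxel_volume()] it was computed from.
#' @return list with `dc` (per-endpoint diameters, m), `mean_dc`,
#'   `endpoint_nodes`, and `border_flagged`.
#' @export
terminal_thickness <- function(skeleton, volume) {
  ep <- which(skeleton$nodes$endpoint & !skeleton$nodes$root)
  # a tip only counts as a terminal branch if its incident path is longer
  # than 1.5x its own inscribed radius; the core node of an unbranched dome
  # or ball fails this and the colony is reported as branchless
  if (length(ep)) {
    elen <- vapply(ep, function(v) {
      eids <- skeleton$edges$from == v | skeleton$edges$to == v
      if (!any(eids)) 0 else max(skeleton$edges$length[eids])
    }, 0)
    ep <- ep[elen >= 1.5 * skeleton$nodes$radius[ep]]
  }
  if (!length(ep))
    stop("no terminal branches: the skeleton has no branch endpoints (degenerate, e.g. a sphere)")
  dims <- dim(volume$mask)
  dc <- 2 * skeleton$nodes$radius[ep]
  idx <- skeleton$voxel_index[ep, , drop = FALSE]
  # endpoint on the volume border: the branch is cropped, dc unreliable
  border <- idx[, 1] <= 1 | idx[, 1] >= dims[1] |
            idx[, 2] <= 1 | idx[, 2] >= dims[2] |
            idx[, 3] <= 1 | idx[, 3] >= dims[3]
  keep <- dc[!border]
  if (!length(keep)) stop("all endpoints lie on the volume border")
  list(dc = dc, mean_dc = mean(keep), endpoint_nodes = ep,
       border_flagged = ep[border])
}

#' Branch symmetry angles
#'
#' Orientation of every skeleton node relative to the root `v0`: `h_angle`
#' is the angle between `d = v_k - v0` and its projection on the horizontal
#' substratum plane `P_xy` through the root (0 deg = horizontal, 90 deg =
#' straight up); `v_angle` is the angle between `d` and its projection on
#' the vertical plane `P_yz` orthogonal to the flow (0 deg = cross-stream,
#' 90 deg = streamwise).  A colony with branches at 45 deg elevation in all
#' directions has mean angles near 45 deg and `h + v` near 90 deg for
#' streamwise-tilted nodes.
#'
#' @param skeleton a `skeleton_graph`.
#' @param flow_axis unit vector of the flow direction (must be horizontal).
#' @return list with per-node `h_angle` and `v_angle` (degrees, in
#'   `[0, 90]`), their means, and the node indices used.
#' @export
symmetry_angles <- function(skeleton, flow_axis = c(1, 0, 0)) {
  flow_axis <- flow_axis / sqrt(sum(flow_axis^2))
  if (abs(flow_axis[3]) > 1e-9)
    stop("flow_axis must be orthogonal to the vertical (z) axis")
  v0 <- unlist(skeleton$nodes[skeleton$root, c("x", "y", "z")])
  pts <- skeleton_points(skeleton)
  d <- sweep(pts, 2, v0)
  nrm <- sqrt(rowSums(d^2))
  ok <- nrm > max(1e-12, min(skeleton$pitch %||% 1e-12) / 2)
  if (!any(ok)) stop("skeleton has no points distinct from the root")
  d <- d[ok, , drop = FALSE]; nrm <- nrm[ok]
  h <- asin(pmin(abs(d[, 3]) / nrm, 1)) * 180 / pi
  v <- asin(pmin(abs(d %*% flow_axis) / nrm, 1)) * 180 / pi
  list(h_angle = as.numeric(h), v_angle = as.numeric(v),
       mean_h = mean(h), mean_v = mean(v), n = sum(ok))
}

#' Streamwise symmetry magnitude
#'
#' Scalar projection of each node's position vector (relative to the root)
#' onto the horizontal direction towards an upstream reference point:
#' `sm_k = |v_k - v0| cos(angle)`, positive for upstream-leaning nodes.
#' Mirror-symmetric colonies have node pairs whose projections negate each
#' other, so the signed sum is near zero; branches crowded upstream push
#' the signed mean positive.  The mean magnitude `mean |sm_k|` is reported
#' alongside (the scale of the Sm_mag summaries), since the symmetry
#' criterion itself uses the signed sum.
#'
#' @param skeleton a `skeleton_graph`.
#' @param upstream_ref 3D reference point in the upstream direction (for
#'   no-flow colonies an arbitrary horizontal reference).
#' @return list with per-node `sm` (m), `signed_mean`, `signed_sum`,
#'   `mean_magnitude`, and node indices.
#' @export
symmetry_magnitude <- function(skeleton, upstream_ref) {
  v0 <- unlist(skeleton$nodes[skeleton$root, c("x", "y", "z")])
  sproj <- c(upstream_ref[1], upstream_ref[2], v0[3])  # project s onto P_xy
  u <- sproj - v0
  un <- sqrt(sum(u^2))
  if (un == 0)
    stop("degenerate upstream reference: its projection coincides with the root")
  u <- u / un
  pts <- skeleton_points(skeleton)
  d <- sweep(pts, 2, v0)
  keep <- sqrt(rowSums(d^2)) > max(1e-12, min(skeleton$pitch %||% 1e-12) / 2)
  d <- d[keep, , drop = FALSE]
  sm <- as.numeric(d %*% u)
  list(sm = sm, signed_mean = mean(sm), signed_sum = sum(sm),
       mean_magnitude = mean(abs(sm)), n = sum(keep))
}

#' Distribution statistics for symmetry angles
#'
#' Sample mean with a t-based 95% confidence interval, adjusted
#' Fisher-Pearson skewness, and excess kurtosis (both bias-corrected), the
#' summaries used to regress angle distributions against the branch Peclet
#' number.
#'
#' @param angles numeric vector (>= 3 values, non-constant).
#' @param conf confidence level (default 0.95).
#' @return list with `mean`, `ci` (length 2), `skewness`, `kurtosis`, `n`.
#' @export
angle_distribution_stats <- function(angles, conf = 0.95) {
  n <- length(angles)
  if (n < 3) stop("need at least 3 values")
  if (sd(angles) == 0)
    stop("zero variance: skewness and kurtosis are undefined for a constant sample")
  m <- mean(angles)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(angles) / sqrt(n)
  list(mean = m, ci = c(m - half, m + half),
       skewness = e1071::skewness(angles, type = 2),
       kurtosis = e1071::kurtosis(angles, type = 2),
       n = n)
}

#' Assemble a full morphometric report
#'
#' Runs the complete morphometric pipeline on a colony -- a
#' [voxel_volume()], a [tri_surface()] (voxelized at `pitch`), or a
#' `growth_run` -- and returns one record of the standard summaries:
#' surface area, volume, surface/volume ratio, terminal-branch thickness
#' `dc`, symmetry angles, symmetry magnitude, their distribution
#' statistics, and the branch-scale `Pe` and `Re` recomputed from the flow
#' configuration (`Pe_branch = u dc / D`, `Re_branch = rho u dc / mu`).
#'
#' @param x colony input (volume, surface, or `growth_run`).
#' @param u_mean mean flow speed (m/s).
#' @param D diffusion coefficient (m^2/s).
#' @param mu dynamic viscosity (Pa s).
#' @param rho fluid density (kg/m^3).
#' @param flow_axis flow direction (horizontal unit vector).
#' @param upstream_ref upstream reference point; default one metre upstream
#'   of the root along `-flow_axis`.
#' @param pitch voxelization pitch when `x` is a surface (default: fine
#'   enough to resolve expected branches, extent/96).
#' @param prune_factor passed to [skeletonize()].
#' @return object of class `morph_report` (a one-row data frame plus
#'   attribute `detail` with the per-node lists).
#' @export
morph_report <- function(x, u_mean = 0, D = 1e-3, mu = 5e-2, rho = 1000,
                         flow_axis = c(1, 0, 0), upstream_ref = NULL,
                         pitch = NULL, prune_factor = 2) {
  area <- volume_m3 <- NA_real_
  if (inherits(x, "growth_run")) x <- x$final
  if (inherits(x, "tri_surface")) {
    av <- surface_area_volume(x)
    area <- av[["area"]]; volume_m3 <- av[["volume"]]
    if (is.null(pitch))
      pitch <- max(apply(x$vertices, 2, function(z) diff(range(z)))) / 96
    vol <- mesh_to_volume(x, pitch)
    vol <- largest_component(vol)
  } else if (inherits(x, "voxel_volume")) {
    vol <- x
    cellv <- prod(vol$pitch)
    volume_m3 <- sum(vol$mask) * cellv
    area <- voxel_surface_area(vol)
  } else stop("unsupported input for morph_report")
  skel <- skeletonize(vol, prune_factor = prune_factor)
  tt <- tryCatch(terminal_thickness(skel, vol), error = function(e) NULL)
  # branchless colony: use the largest inscribed sphere of the whole solid
  # as the characteristic thickness (the skeleton's maximal radius)
  if (is.null(tt))
    tt <- list(dc = numeric(0), mean_dc = 2 * max(skel$nodes$radius))
  ang <- symmetry_angles(skel, flow_axis)
  v0 <- unlist(skel$nodes[skel$root, c("x", "y", "z")])
  if (is.null(upstream_ref)) upstream_ref <- v0 - flow_axis
  sm <- symmetry_magnitude(skel, upstream_ref)
  hstat <- tryCatch(angle_distribution_stats(ang$h_angle),
                    error = function(e) NULL)
  vstat <- tryCatch(angle_distribution_stats(ang$v_angle),
                    error = function(e) NULL)
  mean_dc <- tt$mean_dc
  rep <- data.frame(
    velocity = u_mean, dynamic_viscosity = mu, fluid_density = rho,
    diffusion_coefficient = D,
    dc = mean_dc,
    pe_branch = if (u_mean == 0) 0 else peclet_number(u_mean, mean_dc, D),
    re_branch = reynolds_number(rho, u_mean, mean_dc, mu),
    n_terminal = length(tt$dc),
    surface_area = area, volume = volume_m3, sv_ratio = area / volume_m3,
    h_angle_mean = ang$mean_h, v_angle_mean = ang$mean_v,
    sm_mag_mean = sm$mean_magnitude, sm_signed_mean = sm$signed_mean,
    sm_signed_sum = sm$signed_sum,
    h_skewness = if (is.null(hstat)) NA_real_ else hstat$skewness,
    h_kurtosis = if (is.null(hstat)) NA_real_ else hstat$kurtosis,
    v_skewness = if (is.null(vstat)) NA_real_ else vstat$skewness,
    v_kurtosis = if (is.null(vstat)) NA_real_ else vstat$kurtosis,
    n_endpoints = length(tt$dc))
  attr(rep, "detail") <- list(skeleton = skel, thickness = tt, angles = ang,
                              symmetry = sm)
  class(rep) <- c("morph_report", class(rep))
  rep
}

# exposed-face count surface area of a binary volume
voxel_surface_area <- function(volume) {
  m <- volume$mask
  d <- dim(m); p <- volume$pitch
  ax <- (m[-1, , , drop = FALSE] != m[-d[1], , , drop = FALSE])
  area_x <- (sum(ax) + sum(m[1, , ]) + sum(m[d[1], , ])) * p[2] * p[3]
  ay <- (m[, -1, , drop = FALSE] != m[, -d[2], , drop = FALSE])
  area_y <- (sum(ay) + sum(m[, 1, ]) + sum(m[, d[2], ])) * p[1] * p[3]
  az <- (m[, , -1, drop = FALSE] != m[, , -d[3], drop = FALSE])
  area_z <- (sum(az) + sum(m[, , 1]) + sum(m[, , d[3]])) * p[1] * p[2]
  area_x + area_y + area_z
}
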