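#' Run configuration
#'
#' Experiments are described by a nested configuration (YAML file or list)
#' whose blocks mirror the model parameters by their field names: `fluid`
#' (velocity, dynamic_viscosity, fluid_density), `transport`
#' (diffusion_coefficient, boundary_concentration, sampling_distance),
#' `growth` (L_max, K, n, surface_diffusion, tau_s, steps, target_edge),
#' `domain` (extent, n), and `colony` (diameter, clip_fraction).  All
#' quantities are SI.  Every block is validated against the module
#' constructors before any computation starts.
#'
#' @param config a YAML path or a nested list.
#' @return a validated config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  defaults <- list(
    name = "run", mode = "grow", output_dir = NULL, verbose = FALSE,
    domain = list(extent = c(0.3, 0.3, 0.2), n = c(30, 30, 20)),
    fluid = list(velocity = 0.05, dynamic_viscosity = 5e-2,
                 fluid_density = 1000, tolerance = 1e-3,
                 max_iterations = 3000),
    transport = list(diffusion_coefficient = 1e-3,
                     boundary_concentration = 1.0,
                     sampling_distance = NULL, tolerance = 1e-6),
    growth = list(L_max = 1e-3, K = 1.0, n = 1.2, surface_diffusion = 3e-4,
                  tau_s = NULL, steps = 40, target_edge = 4e-3,
                  form = "hill"),
    colony = list(diameter = 0.06, clip_fraction = 1 / 6),
    fixtures = list(), morph = list())
  cfg <- modifyList(defaults, cfg)
  # build (and thereby validate) the module parameter objects
  cfg$.fluid <- fluid_params(mu = cfg$fluid$dynamic_viscosity,
                             rho = cfg$fluid$fluid_density,
                             u0 = cfg$fluid$velocity,
                             tol = cfg$fluid$tolerance,
                             maxit = cfg$fluid$max_iterations)
  cfg$.transport <- transport_params(D = cfg$transport$diffusion_coefficient,
                                     cb = cfg$transport$boundary_concentration,
                                     l = cfg$transport$sampling_distance,
                                     tol = cfg$transport$tolerance)
  cfg$.growth <- growth_params(L_max = cfg$growth$L_max, K = cfg$growth$K,
                               n = cfg$growth$n,
                               D_s = cfg$growth$surface_diffusion,
                               tau_s = cfg$growth$tau_s,
                               steps = cfg$growth$steps,
                               target_edge = cfg$growth$target_edge,
                               form = cfg$growth$form)
  cfg$.domain <- simulation_domain(extent = unlist(cfg$domain$extent),
                                   n = unlist(cfg$domain$n))
  class(cfg) <- "run_config"
  cfg
}

log_jsonl <- function(path, record) {
  cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n", sep = "",
      file = path, append = TRUE)
}

#' Run a configured experiment
#'
#' Executes the configured mode (`grow`, `flow`, `transport`, `morph` or
#' `synth`), writing into the output directory: a copy of the resolved
#' configuration, a line-delimited JSON log, per-step statistics, the final
#' colony mesh (PLY with per-vertex flux), and a morphometric report CSV.
#'
#' @param config YAML path, list, or `run_config`.
#' @param output_dir overrides the configured output directory.
#' @return the results list, invisibly; its `output_dir` element names the
#'   run directory.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  out <- output_dir %||% cfg$output_dir %||%
    file.path(tempdir(), paste0("coralmorph-", cfg$name))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  keep <- cfg[setdiff(names(cfg), grep("^\\.", names(cfg), value = TRUE))]
  yaml::write_yaml(keep, file.path(out, "config.yaml"))
  logf <- file.path(out, "log.jsonl")
  res <- list(output_dir = out, mode = cfg$mode)
  t0 <- Sys.time()
  log_jsonl(logf, list(event = "start", mode = cfg$mode, name = cfg$name,
                       time = format(t0)))
  if (cfg$mode == "grow") {
    run <- grow_colony(domain = cfg$.domain, fluid = cfg$.fluid,
                       transport = cfg$.transport, growth = cfg$.growth,
                       flow = cfg$fluid$velocity > 0,
                       colony_args = list(diameter = cfg$colony$diameter,
                                          clip_fraction = cfg$colony$clip_fraction),
                       keep_history = FALSE, verbose = isTRUE(cfg$verbose))
    write_ply(run$final, file.path(out, "final.ply"))
    if (!is.null(run$stats)) {
      write.csv(run$stats, file.path(out, "steps.csv"), row.names = FALSE)
      for (s in seq_len(nrow(run$stats)))
        log_jsonl(logf, c(list(event = "step"), as.list(run$stats[s, ])))
    }
    rep <- tryCatch(
      morph_report(run, u_mean = cfg$fluid$velocity,
                   D = cfg$transport$diffusion_coefficient,
                   mu = cfg$fluid$dynamic_viscosity,
                   rho = cfg$fluid$fluid_density),
      error = function(e) {
        log_jsonl(logf, list(event = "morph_skipped",
                             reason = conditionMessage(e)))
        NULL
      })
    if (!is.null(rep))
      write.csv(as.data.frame(rep), file.path(out, "morph_report.csv"),
                row.names = FALSE)
    res$run <- run; res$report <- rep
  } else if (cfg$mode == "flow") {
    col <- make_initial_colony(cfg$colony$diameter,
                               target_edge = cfg$growth$target_edge,
                               center_xy = cfg$.domain$extent[1:2] / 2,
                               clip_fraction = cfg$colony$clip_fraction)
    dom <- voxelize_colony(col, cfg$.domain)
    ff <- solve_flow(dom, cfg$.fluid)
    write_vtk_field(cell_speed(ff, dom), file.path(out, "speed.vtk"),
                    dom$pitch, dom$origin, "speed")
    res$flow <- ff
  } else if (cfg$mode == "transport") {
    col <- make_initial_colony(cfg$colony$diameter,
                               target_edge = cfg$growth$target_edge,
                               center_xy = cfg$.domain$extent[1:2] / 2,
                               clip_fraction = cfg$colony$clip_fraction)
    dom <- voxelize_colony(col, cfg$.domain)
    ff <- if (cfg$fluid$velocity > 0) solve_flow(dom, cfg$.fluid) else NULL
    cf <- solve_transport(dom, ff, cfg$.transport)
    fx <- absorbed_flux(col, cf, cfg$.transport, dom)
    write_nrrd(array(cf$c, dim = dom$n), file.path(out, "concentration.nrrd"),
               pitch = dom$pitch, origin = dom$origin)
    write_flux_csv(col, fx, file.path(out, "flux.csv"))
    res$conc <- cf; res$flux <- fx
  } else if (cfg$mode == "morph") {
    input <- cfg$morph$input
    x <- if (grepl("\\.nrrd$", input)) read_nrrd(input)
         else if (grepl("\\.ply$", input)) read_ply(input)
         else if (grepl("\\.off$", input)) read_off(input)
         else stop("unsupported morph input: ", input)
    rep <- morph_report(x, u_mean = cfg$fluid$velocity,
                        D = cfg$transport$diffusion_coefficient,
                        mu = cfg$fluid$dynamic_viscosity,
                        rho = cfg$fluid$fluid_density)
    write.csv(as.data.frame(rep), file.path(out, "morph_report.csv"),
              row.names = FALSE)
    res$report <- rep
  } else if (cfg$mode == "synth") {
    spec <- do.call(fixture_spec, cfg$fixtures)
    fx <- make_branching_volume(spec)
    write_nrrd(fx$volume, file.path(out, "fixture.nrrd"))
    jsonlite::write_json(list(truth = fx$truth,
                              base = attr(fx$truth, "base")),
                         file.path(out, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    res$fixture <- fx
  } else stop("unknown mode: ", cfg$mode)
  log_jsonl(logf, list(event = "done",
                       elapsed_s = as.numeric(Sys.time() - t0, units = "secs")))
  invisible(res)
}

# set a parameter by bare name in whichever config block defines it
set_config_parameter <- function(cfg, parameter, value) {
  if (grepl("\\.", parameter)) {
    parts <- strsplit(parameter, "\\.")[[1]]
    cfg[[parts[1]]][[parts[2]]] <- value
    return(cfg)
  }
  hit <- FALSE
  for (block in c("fluid", "transport", "growth", "domain", "colony",
                  "fixtures")) {
    if (parameter %in% names(cfg[[block]])) {
      cfg[[block]][[parameter]] <- value
      hit <- TRUE
    }
  }
  if (!hit) stop("parameter not found in any config block: ", parameter)
  cfg
}

#' Parameter sweep over growth runs
#'
#' Runs one growth experiment per parameter value (e.g. the
#' diffusion-coefficient sweep that raises the Peclet number by decades)
#' and collates the morphometric trend table: `Pe_branch`, surface/volume
#' ratio, symmetry magnitude and symmetry angles per run.  Failed runs are
#' recorded and the sweep continues.
#'
#' @param config base configuration (YAML path or list).
#' @param parameter parameter name, e.g. `"diffusion_coefficient"` or
#'   `"growth.n"`.
#' @param values vector of values to sweep.
#' @param output_dir directory for the per-run outputs and the collated
#'   `sweep.csv`.
#' @return data frame with one row per value.
#' @export
sweep_parameter <- function(config, parameter, values, output_dir = NULL) {
  if (!length(values)) stop("empty sweep values")
  cfg0 <- if (inherits(config, "run_config")) config else load_run_config(config)
  out <- output_dir %||% cfg0$output_dir %||%
    file.path(tempdir(), paste0("coralmorph-sweep-", cfg0$name))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    raw <- cfg0[setdiff(names(cfg0), grep("^\\.", names(cfg0), value = TRUE))]
    raw <- set_config_parameter(raw, parameter, values[i])
    raw$name <- sprintf("%s-%s-%g", cfg0$name, gsub("\\.", "-", parameter),
                        values[i])
    class(raw) <- "list"
    rows[[i]] <- tryCatch({
      res <- run_experiment(load_run_config(raw),
                            output_dir = file.path(out, raw$name))
      rep <- res$report
      data.frame(value = values[i], status = "ok",
                 pe_branch = rep$pe_branch, re_branch = rep$re_branch,
                 dc = rep$dc, sv_ratio = rep$sv_ratio,
                 sm_mag_mean = rep$sm_mag_mean,
                 sm_signed_mean = rep$sm_signed_mean,
                 h_angle_mean = rep$h_angle_mean,
                 v_angle_mean = rep$v_angle_mean)
    }, error = function(e) {
      data.frame(value = values[i], status = conditionMessage(e),
                 pe_branch = NA, re_branch = NA, dc = NA, sv_ratio = NA,
                 sm_mag_mean = NA, sm_signed_mean = NA, h_angle_mean = NA,
                 v_angle_mean = NA)
    })
  }
  collated <- do.call(rbind, rows)
  write.csv(collated, file.path(out, "sweep.csv"), row.names = FALSE)
  collated
}
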