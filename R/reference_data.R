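#' Bundled colony parameter reference table
#'
#' Published parameter sets and morphometric summaries for simulated
#' colonies (the diffusion-coefficient sweep SIM_NO_FLOW, SIM_FLOW_D1-D5)
#' and CT-scanned Pocillopora verrucosa colonies grown in flume experiments
#' (CT_xxx, TS_xxx).  Columns: flow velocity (m/s), dynamic viscosity
#' (Pa s), fluid density (kg/m^3), diffusion coefficient (m^2/s), surface
#' diffusion coefficient (m^2/s), mean terminal-branch diameter `dc` (m),
#' branch Peclet and Reynolds numbers, surface area (m^2), volume (m^3),
#' surface/volume ratio (1/m), and mean symmetry magnitude (m).  Used for
#' worked-example checks of the dimensionless numbers and ratios.
#'
#' @return data frame with one row per colony.
#' @export
colony_reference_table <- function() {
  read.csv(system.file("extdata", "colony_parameters.csv",
                       package = "coralmorph"),
           stringsAsFactors = FALSE)
}
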