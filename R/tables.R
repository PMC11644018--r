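#' Reference state points: liquid to supercritical water
#'
#' Seven (temperature, density, pressure) state points spanning ambient
#' water to low-density supercritical fluid, transcribed from a published
#' NVE molecular-dynamics study of flexible 3-site water.  The density was
#' the NVE input; `T_sim_K`/`T_sim_sd_K` give the realised run temperature.
#'
#' @return data.frame: `T_K`, `rho_kg_L`, `P_MPa`, `T_sim_K`, `T_sim_sd_K`.
#' @export
hb_state_points <- function() {
  read.delim(system.file("extdata", "state_points.tsv",
                         package = "hbkinetics"),
             comment.char = "#")
}

#' Reference hydrogen-bond and monomer lifetimes
#'
#' Mean continuous, intermittent, and monomer (non-bonded molecule)
#' lifetimes at the seven state points of [hb_state_points()], with their
#' uncertainties (95% Student-t half-widths for the bond lifetimes, one
#' standard deviation for the monomer lifetimes), transcribed from the same
#' published study.  These are fixture inputs for the fitting layer; the
#' package does not claim to reproduce them by MD at desk scale.
#'
#' @return data.frame: `T_K`, `P_MPa`, `tau_c_fs`, `tau_c_err`,
#'   `tau_int_fs`, `tau_int_err`, `tau_nb_fs`, `tau_nb_err`.
#' @export
hb_lifetimes <- function() {
  read.delim(system.file("extdata", "hb_lifetimes.tsv",
                         package = "hbkinetics"),
             comment.char = "#")
}
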