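#' Reaction rate vector of the hepatocyte network
#'
#' Evaluates all reaction rates at a given concentration state. Enzymatic
#' reactions follow irreversible Michaelis-Menten kinetics (GST and GPX are
#' bi-substrate with multiplicative saturation terms), passive diffusion is
#' linear in the transmembrane gradient, non-specific binding is reversible
#' mass action, and ROS synthesis is first order in protein-bound NAPQI.
#' The lobule zonation factor multiplies the CYP3A4 Vmax only.
#'
#' @param conc named species vector (uM); see [cell_initial_state()]
#' @param profile an [enzyme_profile()]
#' @param zone_factor dimensionless CYP3A4 multiplier, > 0
#' @return named rate vector, umol/L_cell/min
#' @export
reaction_rates <- function(conc, profile, zone_factor = 1) {
  conc <- .species_vector(conc)
  if (any(conc < 0)) stop("negative concentration")
  if (!is.finite(zone_factor) || zone_factor <= 0)
    stop("zone_factor must be > 0")
  .reaction_rates_cpp(conc, .profile_vector(profile), zone_factor)
}

#' Time derivative of one hepatocyte's species vector
#'
#' Returns `N %*% v`: the stoichiometric matrix applied to the reaction
#' rates. For a dead cell all derivatives are zero (intracellular functions
#' stop; extracellular slots evolve only through sinusoidal transport,
#' which is handled by the transport module).
#'
#' @inheritParams reaction_rates
#' @param alive logical; dead cells are frozen
#' @param ext_scale volume ratio V_cell/V_ext applied to extracellular
#'   rows so that amounts (not concentrations) are conserved across the
#'   membrane
#' @param clamp_apap_ext hold the extracellular APAP reservoir fixed
#'   (in-vitro exposure mode)
#' @return named derivative vector, uM/min
#' @export
cell_rhs <- function(conc, profile, zone_factor = 1, alive = TRUE,
                     ext_scale = 1, clamp_apap_ext = FALSE) {
  conc <- .species_vector(conc)
  .cell_rhs_cpp(conc, .profile_vector(profile), zone_factor, alive,
                ext_scale, clamp_apap_ext)
}

#' Basal hepatocyte state
#'
#' All species zero except glutathione at its basal steady state, where
#' synthesis (GSS, constant flux) balances degradation (GGT,
#' Michaelis-Menten): `GSH_0 = km_ggt * vmax_gss / (vmax_ggt - vmax_gss)`.
#'
#' @param profile an [enzyme_profile()]
#' @return named species vector (uM)
#' @export
cell_initial_state <- function(profile = enzyme_profile()) {
  p <- unclass(profile)
  s <- setNames(numeric(17), .hepasim_species())
  if (p[["vmax_ggt"]] <= p[["vmax_gss"]])
    stop("GGT capacity must exceed GSS flux for a finite basal GSH")
  s[["GSH"]] <- p[["km_ggt"]] * p[["vmax_gss"]] /
    (p[["vmax_ggt"]] - p[["vmax_gss"]])
  s
}

#' Basal glutathione concentration of a profile
#' @inheritParams cell_initial_state
#' @return basal GSH, uM
#' @export
basal_gsh <- function(profile = enzyme_profile()) {
  cell_initial_state(profile)[["GSH"]]
}

.species_vector <- function(conc) {
  nm <- .hepasim_species()
  if (is.null(names(conc))) {
    if (length(conc) != length(nm)) stop("expected 17 species")
    return(setNames(as.numeric(conc), nm))
  }
  if (!all(nm %in% names(conc)))
    stop("species vector is missing: ",
         paste(setdiff(nm, names(conc)), collapse = ", "))
  setNames(as.numeric(conc[nm]), nm)
}

#' Simulate one hepatocyte under an extracellular APAP exposure
#'
#' Integrates the cell network with the extracellular APAP concentration
#' clamped to a piecewise-constant schedule (the culture medium is treated
#' as an infinite reservoir). Uses an embedded adaptive Runge-Kutta
#' (Cash-Karp 4/5) integrator; the running peak of intracellular H2O2 is
#' tracked inside the integrator (between output samples).
#'
#' @param c0 initial species vector, e.g. [cell_initial_state()]
#' @param profile an [enzyme_profile()]
#' @param exposure either a single concentration (uM, constant) or a
#'   two-column matrix/data.frame `(time_min, conc_uM)` interpreted as a
#'   piecewise-constant schedule starting at time 0
#' @param duration simulation length, min
#' @param zone_factor CYP3A4 zonation multiplier
#' @param out_dt output sampling interval, min
#' @param ext_scale volume ratio V_cell/V_medium for the non-clamped
#'   extracellular species (conjugates released to the medium)
#' @param rtol,atol integrator tolerances
#' @return object of class `cell_trajectory`: list with `time`, `states`
#'   (matrix, one column per species) and `peak_h2o2`
#' @export
simulate_cell <- function(c0, profile, exposure, duration,
                          zone_factor = 1, out_dt = 1,
                          ext_scale = 1e-3, rtol = 1e-6, atol = 1e-4) {
  if (duration <= 0) stop("duration must be > 0")
  c0 <- .species_vector(c0)
  if (is.numeric(exposure) && length(exposure) == 1) {
    e_t <- 0; e_v <- exposure
  } else {
    exposure <- as.matrix(exposure)
    e_t <- exposure[, 1]; e_v <- exposure[, 2]
    if (is.unsorted(e_t)) stop("exposure times must be sorted")
  }
  if (any(e_v < 0)) stop("exposure concentrations must be >= 0")
  out <- .simulate_cell_cpp(c0, .profile_vector(profile), zone_factor,
                            as.numeric(e_t), as.numeric(e_v), duration,
                            out_dt, ext_scale, rtol, atol)
  structure(out, class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("cell trajectory:", length(x$time), "samples over",
      max(x$time), "min; peak H2O2 =", signif(x$peak_h2o2, 4), "uM\n")
  invisible(x)
}
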