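#' Default run configuration
#'
#' The canonical structured configuration covering every tunable of the
#' model: the cell kinetic constants, injury parameters, sinusoid/lobule
#' geometry, zonation, PBPK block, dose regimen, in-vitro setup and solver
#' controls. All defaults reproduce the package's reference
#' parameterisation; [write_default_config()] dumps them for diffing.
#'
#' @return nested list of class `hepasim_config`
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    cell = as.list(enzyme_profile_defaults()),
    injury = list(h2o2_crit = 4000, gsh_depletion_fraction = 0.1,
                  delay_min = 0, delay_max = 1, sensitivity_floor = 0.05,
                  hazard_scale = 5),
    geometry = list(n_sections = 16L, cells_per_section = 4L,
                    l_h_um = 23, r_um = 5, u_x_mm_s = 0.05,
                    temperature_K = 273, viscosity_Pa_s = 3e-3,
                    radius_gyration_A = 2.99, fu = 0.75),
    zonation = list(boundaries = c(1 / 3, 2 / 3),
                    multipliers = c(1.0, 1.0, 1.3)),
    pbpk = list(
      flows = list(adipose = 0.56, liver = 1.3, wpt = 3.5, ppt = 1.63,
                   blood = 6.4),
      volumes = list(adipose = 28.0, liver = 1.82, wpt = 5.68, ppt = 35,
                     blood = 5.7, plasma = 3.4),
      partition = list(adipose = 0.25, liver = 0.774, wpt = 0.774,
                       ppt = 0.66, blood = 0.774, plasma = 0.774),
      urinary_cl = 0.016, parenchymal_fraction = 0.8, xi = 0.75),
    regimen = list(dose_mg_kg = 393, time_min = 0, weight_kg = 73,
                   fr_ing = 0.9, k_gut = 0.025),
    in_vitro = list(n_cells = 200L,
                    concentrations = c(1000, 2000, 2828, 4000, 5657,
                                       8000, 16000),
                    duration_min = 720, cv = 0.2),
    calibration = list(target_lc50 = 4000, h2o2_target = 4000),
    simulation = list(duration_min = 2000, n_sub = 65L,
                      rtol = 1e-6, atol = 1e-4)
  )
  class(cfg) <- c("hepasim_config", "list")
  cfg
}

#' Read a configuration file with validation
#'
#' Reads a YAML configuration and merges it over the defaults. Unknown
#' keys (at any level) are rejected with the offending key named; basic
#' positivity constraints are enforced.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @param overrides named list of `section$key` overrides applied last
#' @return validated `hepasim_config`
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    .check_keys(user, cfg, "")
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(overrides)) {
    .check_keys(overrides, cfg, "")
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
  class(cfg) <- c("hepasim_config", "list")
  cfg
}

.check_keys <- function(user, ref, prefix) {
  if (!is.list(user)) return(invisible())
  bad <- setdiff(names(user), names(ref))
  if (length(bad))
    stop("unknown configuration key: ", prefix, bad[1], call. = FALSE)
  for (nm in names(user))
    if (is.list(ref[[nm]]))
      .check_keys(user[[nm]], ref[[nm]], paste0(prefix, nm, "$"))
  invisible()
}

#' Validate a configuration
#' @param cfg a `hepasim_config`
#' @return the config, invisibly; stops with the offending field on error
#' @export
validate_config <- function(cfg) {
  must_pos <- function(x, nm) {
    if (any(!is.finite(as.numeric(x))) || any(as.numeric(x) <= 0))
      stop("configuration field must be > 0: ", nm, call. = FALSE)
  }
  for (nm in names(cfg$pbpk$volumes)) must_pos(cfg$pbpk$volumes[[nm]],
                                               paste0("pbpk$volumes$", nm))
  for (nm in names(cfg$pbpk$flows)) must_pos(cfg$pbpk$flows[[nm]],
                                             paste0("pbpk$flows$", nm))
  for (nm in names(cfg$pbpk$partition))
    must_pos(cfg$pbpk$partition[[nm]], paste0("pbpk$partition$", nm))
  must_pos(cfg$geometry$l_h_um, "geometry$l_h_um")
  must_pos(cfg$geometry$r_um, "geometry$r_um")
  must_pos(cfg$geometry$u_x_mm_s, "geometry$u_x_mm_s")
  must_pos(cfg$geometry$fu, "geometry$fu")
  must_pos(cfg$regimen$weight_kg, "regimen$weight_kg")
  if (any(unlist(cfg$cell) < 0))
    stop("configuration field must be >= 0: cell kinetic constants",
         call. = FALSE)
  if (cfg$regimen$dose_mg_kg < 0)
    stop("configuration field must be >= 0: regimen$dose_mg_kg",
         call. = FALSE)
  invisible(cfg)
}

#' Write the default configuration to a YAML file
#' @param path output path
#' @return the path, invisibly
#' @export
write_default_config <- function(path = "hepasim-defaults.yaml") {
  yaml::write_yaml(unclass(default_config()), path)
  invisible(path)
}

# ---- constructors from a configuration --------------------------------

config_profile <- function(cfg) do.call(enzyme_profile, cfg$cell)

config_injury <- function(cfg) do.call(injury_parameters, cfg$injury)

config_geometry <- function(cfg) {
  g <- cfg$geometry
  sinusoid_geometry(
    n_sections = g$n_sections, cells_per_section = g$cells_per_section,
    l_h_m = g$l_h_um * 1e-6, r_m = g$r_um * 1e-6,
    u_x_m_s = g$u_x_mm_s * 1e-3,
    d_m2_s = diffusion_coefficient(g$temperature_K, g$viscosity_Pa_s,
                                   g$radius_gyration_A * 1e-10),
    fu = g$fu)
}

config_zonation <- function(cfg)
  zonation_profile(unlist(cfg$zonation$boundaries),
                   unlist(cfg$zonation$multipliers))

config_pbpk <- function(cfg) {
  p <- cfg$pbpk
  pbpk_parameters(flows = unlist(p$flows), volumes = unlist(p$volumes),
                  partition = unlist(p$partition),
                  urinary_cl = p$urinary_cl,
                  parenchymal_fraction = p$parenchymal_fraction,
                  xi = p$xi)
}

config_regimen <- function(cfg) {
  r <- cfg$regimen
  dose_regimen(r$dose_mg_kg, r$time_min, r$weight_kg, r$fr_ing, r$k_gut)
}
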