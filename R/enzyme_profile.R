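#' Hepatocyte enzyme and transporter profile
#'
#' Kinetic parameters of one individual's hepatocyte: Vmax (umol/L_cell/min)
#' and Km (uM) for the metabolic enzymes, transporter capacities, passive
#' permeabilities (1/min, cell-volume normalised), binding rate constants
#' (1/min), the ROS-generation gain coupling protein-bound NAPQI to
#' superoxide synthesis, and the basal H2O2 clearance rate.
#'
#' Defaults: the CYP3A4 and CYP2E1 activities (0.95 and 1.0 umol/L_cell/min)
#' are the reference individual; the remaining constants are package
#' calibration choices at literature-typical magnitudes (APAP oxidation and
#' glucuronidation are low-affinity, mM-scale; sulfation is high-affinity
#' and saturates first; hepatocyte glutathione is mM-scale with a turnover
#' of hours). See the package vignette for the calibration rationale.
#'
#' @param ... named overrides of any parameter (see
#'   [enzyme_profile_defaults()] for names).
#' @return `enzyme_profile` object (named numeric vector).
#' @examples
#' p <- enzyme_profile(vmax_cyp2e1 = 5.0)  # high-CYP2E1 individual
#' @export
enzyme_profile <- function(...) {
  p <- enzyme_profile_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown enzyme profile parameter(s): ",
           paste(bad, collapse = ", "))
    p[names(over)] <- as.numeric(unlist(over))
  }
  validate_enzyme_profile(p)
  class(p) <- "enzyme_profile"
  p
}

#' Default enzyme profile parameters
#' @return named numeric vector of all kinetic constants
#' @export
enzyme_profile_defaults <- function() {
  c(
    vmax_cyp3a4 = 0.95,  km_cyp3a4 = 750,
    vmax_cyp2e1 = 1.0,   km_cyp2e1 = 750,
    vmax_cyp_minor = 0.3, km_cyp_minor = 750,
    vmax_ugt = 60,   km_ugt = 6000,
    vmax_sult = 15,  km_sult = 300,
    vmax_gst = 300,  km_gst_napqi = 50, km_gst_gsh = 300,
    vmax_nqo1 = 1.0, km_nqo1 = 200,
    vmax_gss = 26,
    vmax_ggt = 30,   km_ggt = 1000,
    vmax_gpx = 600,  km_gpx_h2o2 = 100, km_gpx_gsh = 1000,
    vmax_sod = 2000, km_sod = 500,
    vmax_gsr = 150,  km_gsr = 100,
    vmax_uptake = 10, km_uptake = 2000,
    p_apap = 0.5,    p_napqi = 0.3,
    kon_apap = 0.2,  koff_apap = 0.2,
    kon_apaps = 0.5, koff_apaps = 0.1,
    kon_napqi = 2.0, koff_napqi = 0.01,
    k_ros = 1.2,     k_h2o2_clear = 0.05,
    vmax_mrp2 = 50,  km_mrp2 = 1000,
    vmax_mrp34 = 50, km_mrp34 = 1000
  )
}

validate_enzyme_profile <- function(p) {
  expected <- .hepasim_param_names()
  if (!all(expected %in% names(p)))
    stop("enzyme profile is missing: ",
         paste(setdiff(expected, names(p)), collapse = ", "))
  if (any(!is.finite(p)) || any(p < 0))
    stop("all enzyme profile parameters must be finite and >= 0")
  vmax <- p[grep("^vmax_", names(p))]
  for (nm in names(vmax)) {
    km_nm <- sub("^vmax_", "km_", nm)
    if (km_nm %in% names(p) && vmax[[nm]] > 0 && p[[km_nm]] <= 0)
      stop(km_nm, " must be > 0 when ", nm, " > 0")
  }
  invisible(p)
}

# parameter vector in the fixed order expected by the compiled code
.profile_vector <- function(profile) {
  nm <- .hepasim_param_names()
  out <- as.numeric(unclass(profile)[nm])
  if (any(is.na(out))) stop("incomplete enzyme profile")
  out
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cat("hepatocyte enzyme profile (umol/L_cell/min; uM; 1/min)\n")
  print(unclass(x))
  invisible(x)
}

#' Convert a recombinant-enzyme specific activity to a cell-volume Vmax
#'
#' Specific activities measured on recombinant enzymes
#' (nmol drug / nmol enzyme / min) are scaled to cellular activities
#' (umol/L_cell/min) using the microsomal enzyme content, the ratio of
#' microsomal to total cell protein, and the total cell protein per cell
#' volume: `Vmax = a_spec * content * ratio * total_protein / 1000`
#' (the 1/1000 carries nmol to umol).
#'
#' @param a_spec specific activity, nmol/nmol_enzyme/min
#' @param content microsomal enzyme content, nmol_enzyme/g microsomal
#'   protein
#' @param spec an [activity_conversion_spec()]
#' @return Vmax in umol/L_cell/min
#' @examples
#' # 100 pmol/mg microsomal protein = 0.1 nmol/mg = 100 nmol/g
#' convert_specific_activity(2, 100)   # 1.32 umol/L_cell/min
#' @export
convert_specific_activity <- function(a_spec, content,
                                      spec = activity_conversion_spec()) {
  if (any(a_spec < 0) || any(content < 0))
    stop("specific activity and enzyme content must be >= 0")
  enzyme_conc_nmol_per_L <- content * spec$microsomal_ratio *
    spec$total_protein_g_per_L
  a_spec * enzyme_conc_nmol_per_L / 1000
}

#' Cell-protein scaling constants for activity conversion
#'
#' @param total_protein_g_per_L total cell protein per litre of cells
#' @param microsomal_ratio ratio of microsomal to total cell protein
#' @return list with the two constants
#' @export
activity_conversion_spec <- function(total_protein_g_per_L = 30,
                                     microsomal_ratio = 0.22) {
  if (total_protein_g_per_L <= 0 || microsomal_ratio <= 0)
    stop("conversion constants must be > 0")
  list(total_protein_g_per_L = total_protein_g_per_L,
       microsomal_ratio = microsomal_ratio)
}
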