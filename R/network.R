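#' Build the hepatocyte reaction network for APAP metabolism and toxicity
#'
#' Constructs the fixed stoichiometric model of the cellular network: APAP
#' uptake (saturable carrier + passive diffusion), phase II conjugation to
#' the glucuronide (UGT) and sulfate (SULT), CYP-mediated oxidation to NAPQI
#' (CYP3A4, CYP2E1 and a lumped minor-CYP pool), NQO1 back-reduction, GST
#' conjugation of NAPQI with glutathione, non-specific binding pools for
#' APAP, APAPS and NAPQI (protein-bound NAPQI drives ROS synthesis), MRP2
#' (apical, leaves the system) and MRP3/4 (basolateral, returns to the
#' sinusoidal bulk) conjugate export, glutathione synthesis (GSS) and
#' degradation (GGT), and the oxidative-stress branch
#' ROS -> H2O2 (SOD), H2O2 + 2 GSH -> GSSG (GPX), GSSG -> 2 GSH (GSR),
#' plus basal H2O2 clearance.
#'
#' @return An object of class `stoich_model`: a list with `species`
#'   (17 names, 12 intracellular then 5 extracellular), `reactions`
#'   (a data.frame with reaction id, enzyme, rate-law form, and whether the
#'   reaction is membrane transport), and `N`, the integer stoichiometric
#'   matrix (species x reactions).
#' @examples
#' net <- build_network()
#' net$N[, "gst"]   # NAPQI + GSH -> APAPGS
#' @export
build_network <- function() {
  species <- .hepasim_species()
  reactions <- .hepasim_reactions()
  N <- .hepasim_stoich()
  transport <- .hepasim_transport_flags()
  enzyme <- c(
    uptake_active = "carrier", uptake_passive = "passive", ugt = "UGT",
    sult = "SULT", cyp3a4 = "CYP3A4", cyp2e1 = "CYP2E1",
    cyp_minor = "CYP_minor", nqo1 = "NQO1", gst = "GST",
    napqi_binding = "binding", apap_binding = "binding",
    apaps_binding = "binding", mrp2_apapg = "MRP2", mrp2_apaps = "MRP2",
    mrp2_apapgs = "MRP2", mrp34_apapg = "MRP34", mrp34_apaps = "MRP34",
    mrp34_apapgs = "MRP34", napqi_diffusion = "passive", gss = "GSS",
    ggt = "GGT", ros_synthesis = "NAPQI_P", sod = "SOD", gpx = "GPX",
    gsr = "GSR", h2o2_clearance = "basal"
  )
  law <- c(
    uptake_active = "michaelis_menten", uptake_passive = "passive_gradient",
    ugt = "michaelis_menten", sult = "michaelis_menten",
    cyp3a4 = "michaelis_menten", cyp2e1 = "michaelis_menten",
    cyp_minor = "michaelis_menten", nqo1 = "michaelis_menten",
    gst = "bi_substrate_mm", napqi_binding = "mass_action_reversible",
    apap_binding = "mass_action_reversible",
    apaps_binding = "mass_action_reversible",
    mrp2_apapg = "michaelis_menten", mrp2_apaps = "michaelis_menten",
    mrp2_apapgs = "michaelis_menten", mrp34_apapg = "michaelis_menten",
    mrp34_apaps = "michaelis_menten", mrp34_apapgs = "michaelis_menten",
    napqi_diffusion = "passive_gradient", gss = "constant_flux",
    ggt = "michaelis_menten", ros_synthesis = "first_order",
    sod = "michaelis_menten", gpx = "bi_substrate_mm",
    gsr = "michaelis_menten", h2o2_clearance = "first_order"
  )
  out <- list(
    species = species,
    n_intracellular = 12L,
    reactions = data.frame(
      reaction = reactions,
      enzyme = unname(enzyme[reactions]),
      law = unname(law[reactions]),
      transport = unname(transport[reactions]),
      stringsAsFactors = FALSE
    ),
    N = N
  )
  class(out) <- "stoich_model"
  out
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("APAP hepatocyte network:", length(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  cat("  transport reactions:", sum(x$reactions$transport), "\n")
  invisible(x)
}

#' Species carrying the APAP moiety
#'
#' Indicator vector over species marking everything derived from the
#' original APAP molecule (parent, bound pools, NAPQI, conjugates, and
#' their extracellular counterparts). Dotted with any chemical
#' transformation column of the stoichiometric matrix it gives zero;
#' only transport (and MRP2 bile export) moves the moiety out.
#'
#' @param net a `stoich_model` from [build_network()]
#' @return named 0/1 numeric vector over species
#' @export
apap_moiety <- function(net = build_network()) {
  m <- setNames(numeric(length(net$species)), net$species)
  m[c("APAP_cyt", "APAP_B", "NAPQI", "NAPQI_P", "APAPG", "APAPS",
      "APAPS_B", "APAPGS", "APAP_ext", "APAPG_ext", "APAPS_ext",
      "APAPGS_ext", "NAPQI_ext")] <- 1
  m
}
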