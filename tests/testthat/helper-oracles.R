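# Independent R-side oracle for the reaction rate laws, written directly
# from the network descriptor table (no shared code with the compiled
# implementation).
oracle_rates <- function(conc, profile, zone_factor = 1) {
  p <- unclass(profile)
  cpos <- pmax(conc, 0)
  mm <- function(vmax, km, s) vmax * s / (km + s)
  v <- c(
    uptake_active = mm(p[["vmax_uptake"]], p[["km_uptake"]],
                       cpos[["APAP_ext"]]),
    uptake_passive = p[["p_apap"]] * (conc[["APAP_ext"]] -
                                        conc[["APAP_cyt"]]),
    ugt = mm(p[["vmax_ugt"]], p[["km_ugt"]], cpos[["APAP_cyt"]]),
    sult = mm(p[["vmax_sult"]], p[["km_sult"]], cpos[["APAP_cyt"]]),
    cyp3a4 = zone_factor * mm(p[["vmax_cyp3a4"]], p[["km_cyp3a4"]],
                              cpos[["APAP_cyt"]]),
    cyp2e1 = mm(p[["vmax_cyp2e1"]], p[["km_cyp2e1"]], cpos[["APAP_cyt"]]),
    cyp_minor = mm(p[["vmax_cyp_minor"]], p[["km_cyp_minor"]],
                   cpos[["APAP_cyt"]]),
    nqo1 = mm(p[["vmax_nqo1"]], p[["km_nqo1"]], cpos[["NAPQI"]]),
    gst = p[["vmax_gst"]] *
      (cpos[["NAPQI"]] / (p[["km_gst_napqi"]] + cpos[["NAPQI"]])) *
      (cpos[["GSH"]] / (p[["km_gst_gsh"]] + cpos[["GSH"]])),
    napqi_binding = p[["kon_napqi"]] * conc[["NAPQI"]] -
      p[["koff_napqi"]] * conc[["NAPQI_P"]],
    apap_binding = p[["kon_apap"]] * conc[["APAP_cyt"]] -
      p[["koff_apap"]] * conc[["APAP_B"]],
    apaps_binding = p[["kon_apaps"]] * conc[["APAPS"]] -
      p[["koff_apaps"]] * conc[["APAPS_B"]],
    mrp2_apapg = mm(p[["vmax_mrp2"]], p[["km_mrp2"]], cpos[["APAPG"]]),
    mrp2_apaps = mm(p[["vmax_mrp2"]], p[["km_mrp2"]], cpos[["APAPS"]]),
    mrp2_apapgs = mm(p[["vmax_mrp2"]], p[["km_mrp2"]], cpos[["APAPGS"]]),
    mrp34_apapg = mm(p[["vmax_mrp34"]], p[["km_mrp34"]], cpos[["APAPG"]]),
    mrp34_apaps = mm(p[["vmax_mrp34"]], p[["km_mrp34"]], cpos[["APAPS"]]),
    mrp34_apapgs = mm(p[["vmax_mrp34"]], p[["km_mrp34"]],
                      cpos[["APAPGS"]]),
    napqi_diffusion = p[["p_napqi"]] * (conc[["NAPQI_ext"]] -
                                          conc[["NAPQI"]]),
    gss = p[["vmax_gss"]],
    ggt = mm(p[["vmax_ggt"]], p[["km_ggt"]], cpos[["GSH"]]),
    ros_synthesis = p[["k_ros"]] * cpos[["NAPQI_P"]],
    sod = mm(p[["vmax_sod"]], p[["km_sod"]], cpos[["ROS"]]),
    gpx = p[["vmax_gpx"]] *
      (cpos[["H2O2"]] / (p[["km_gpx_h2o2"]] + cpos[["H2O2"]])) *
      (cpos[["GSH"]] / (p[["km_gpx_gsh"]] + cpos[["GSH"]])),
    gsr = mm(p[["vmax_gsr"]], p[["km_gsr"]], cpos[["GSSG"]]),
    h2o2_clearance = p[["k_h2o2_clear"]] * cpos[["H2O2"]]
  )
  v
}

# random non-negative species state for property checks
random_state <- function(scale = 1000) {
  s <- cell_initial_state()
  s[] <- runif(length(s), 0, scale)
  s
}

# a small, fast geometry for transport unit tests
test_geometry <- function(...) sinusoid_geometry(...)
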