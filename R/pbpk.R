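#' Whole-body PBPK parameters
#'
#' Flow-limited compartments for a 73-kg adult: adipose tissue, liver,
#' other well-perfused tissues (WPT), other poorly perfused tissues (PPT),
#' and blood; each carries a blood flow (L/min), a volume (L) and a
#' tissue:blood partition coefficient. The liver additionally receives the
#' gut absorption input and loses APAP to the lobule-derived clearance;
#' urinary excretion acts on blood.
#'
#' @param flows,volumes,partition named vectors over
#'   `adipose, liver, wpt, ppt, blood` (and a `plasma` volume/partition
#'   row kept for reporting)
#' @param urinary_cl urinary clearance, L/min
#' @param parenchymal_fraction parenchymal share of the liver volume used
#'   to scale one lobule to the whole organ
#' @param xi coupling constant of the lobule clearance to the liver
#'   compartment
#' @return `pbpk_parameters` object
#' @export
pbpk_parameters <- function(
    flows = c(adipose = 0.56, liver = 1.3, wpt = 3.5, ppt = 1.63,
              blood = 6.4),
    volumes = c(adipose = 28.0, liver = 1.82, wpt = 5.68, ppt = 35,
                blood = 5.7, plasma = 3.4),
    partition = c(adipose = 0.25, liver = 0.774, wpt = 0.774, ppt = 0.66,
                  blood = 0.774, plasma = 0.774),
    urinary_cl = 0.016, parenchymal_fraction = 0.8, xi = 0.75) {
  stopifnot(all(flows > 0), all(volumes > 0), all(partition > 0),
            urinary_cl >= 0, parenchymal_fraction > 0,
            parenchymal_fraction <= 1, xi > 0)
  structure(list(flows = flows, volumes = volumes, partition = partition,
                 urinary_cl = urinary_cl,
                 parenchymal_fraction = parenchymal_fraction, xi = xi),
            class = "pbpk_parameters")
}

#' Oral dose regimen
#'
#' @param doses_mg_kg vector of oral bolus doses, mg/kg
#' @param times_min administration times, min
#' @param weight_kg body weight, kg
#' @param fr_ing fraction of the ingested dose entering the gut
#' @param k_gut first-order gut-to-liver absorption rate, 1/min
#' @return `dose_regimen` object
#' @export
dose_regimen <- function(doses_mg_kg, times_min = 0, weight_kg = 73,
                         fr_ing = 0.9, k_gut = 0.025) {
  stopifnot(all(doses_mg_kg >= 0), length(times_min) == length(doses_mg_kg),
            weight_kg > 0, fr_ing > 0, fr_ing <= 1, k_gut > 0)
  structure(list(doses_mg_kg = doses_mg_kg, times_min = times_min,
                 weight_kg = weight_kg, fr_ing = fr_ing, k_gut = k_gut),
            class = "dose_regimen")
}

#' Gut absorption dynamics
#'
#' Between boluses the gut amount follows `dQ/dt = -k_gut * Q`; an oral
#' bolus instantaneously adds `fr_ing * weight * dose` to the gut.
#'
#' @param q_gut current gut amount, mg
#' @param regimen a [dose_regimen()]
#' @return `dQ_gut/dt`, mg/min
#' @export
gut_rhs <- function(q_gut, regimen) -regimen$k_gut * q_gut

#' Bolus amount entering the gut for one administration
#' @param regimen a [dose_regimen()]
#' @param i index of the administration
#' @return mg entering the gut
#' @export
gut_bolus <- function(regimen, i = 1)
  regimen$fr_ing * regimen$weight_kg * regimen$doses_mg_kg[i]

#' Flow-limited compartment derivative
#'
#' `V_i dC_i/dt = F_i (C_b - C_i / PC_i)` for a perfusion-rate-limited
#' tissue exchanging with blood.
#'
#' @param c_i tissue concentration, mg/L
#' @param c_b blood concentration, mg/L
#' @param flow blood flow, L/min
#' @param volume tissue volume, L
#' @param pc partition coefficient
#' @return `dC_i/dt`, mg/L/min
#' @export
compartment_rhs <- function(c_i, c_b, flow, volume, pc)
  flow * (c_b - c_i / pc) / volume

#' Liver compartment derivative
#'
#' `V_liv dC_liv/dt = F_liv (C_a - C_liv / PC_liv) + k_gut Q_gut -
#' xi * R_lobule`, with the arterial concentration equal to mixed venous
#' blood and `R_lobule` the lobule elimination rate scaled to the whole
#' parenchyma (mg/min).
#'
#' @param c_liv liver concentration, mg/L
#' @param c_b blood concentration, mg/L
#' @param q_gut gut amount, mg
#' @param lobule_mg_min parenchyma-scaled lobule elimination rate, mg/min
#'   (before multiplication by `xi`)
#' @param pb a [pbpk_parameters()]
#' @param k_gut absorption rate, 1/min
#' @return `dC_liv/dt`, mg/L/min
#' @export
liver_rhs <- function(c_liv, c_b, q_gut, lobule_mg_min, pb,
                      k_gut = 0.025) {
  (pb$flows[["liver"]] * (c_b - c_liv / pb$partition[["liver"]]) +
     k_gut * q_gut - pb$xi * lobule_mg_min) / pb$volumes[["liver"]]
}

# scale factor mapping one lobule's elimination (umol/min) to the whole
# parenchyma: (parenchymal liver volume) / (volume of one lobule's cells)
.lobule_scale <- function(pb, geom, n_sinusoids = 6L) {
  n_cells <- n_sinusoids * geom$n_sections * geom$cells_per_section
  pb$parenchymal_fraction * pb$volumes[["liver"]] /
    (n_cells * geom$v_cell_L)
}

# PBPK state derivative; y = (Qgut, C_adipose, C_wpt, C_ppt, C_liv, C_b,
# urinary, removed); lobule elimination held constant over the sub-step.
.pbpk_rhs <- function(y, pb, k_gut, liver_elim_mg_min) {
  fl <- pb$flows; vol <- pb$volumes; pc <- pb$partition
  q_gut <- y[1]; c_ad <- y[2]; c_wpt <- y[3]; c_ppt <- y[4]
  c_liv <- y[5]; c_b <- y[6]
  tissues <- c("adipose", "wpt", "ppt", "liver")
  venous_return <- fl[["adipose"]] * c_ad / pc[["adipose"]] +
    fl[["wpt"]] * c_wpt / pc[["wpt"]] + fl[["ppt"]] * c_ppt / pc[["ppt"]] +
    fl[["liver"]] * c_liv / pc[["liver"]]
  f_total <- sum(fl[tissues])
  c(
    -k_gut * q_gut,
    compartment_rhs(c_ad, c_b, fl[["adipose"]], vol[["adipose"]],
                    pc[["adipose"]]),
    compartment_rhs(c_wpt, c_b, fl[["wpt"]], vol[["wpt"]], pc[["wpt"]]),
    compartment_rhs(c_ppt, c_b, fl[["ppt"]], vol[["ppt"]], pc[["ppt"]]),
    (fl[["liver"]] * (c_b - c_liv / pc[["liver"]]) + k_gut * q_gut -
       liver_elim_mg_min) / vol[["liver"]],
    (venous_return - f_total * c_b - pb$urinary_cl * c_b) / vol[["blood"]],
    pb$urinary_cl * c_b,
    liver_elim_mg_min
  )
}

.rk4_step <- function(y, h, rhs) {
  k1 <- rhs(y)
  k2 <- rhs(y + h / 2 * k1)
  k3 <- rhs(y + h / 2 * k2)
  k4 <- rhs(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Co-simulate the whole body and the structured liver
#'
#' Macro-stepped co-simulation: the PBPK compartments are advanced with
#' the lobule clearance of the previous step held constant; the lobule is
#' advanced with an inlet equal to the unbound portal concentration (mixed
#' venous blood plus the gut absorption stream, times the fraction
#' unbound); the resulting mean elimination rate, scaled from one lobule
#' to the whole parenchyma and multiplied by `xi`, feeds back into the
#' liver compartment. Death events in the lobule reduce the liver's
#' elimination capacity for the remainder of the run.
#'
#' @param regimen a [dose_regimen()]
#' @param individual list with `profile` (an [enzyme_profile()]) and
#'   optionally `injury` (an [injury_parameters()]; `NULL` disables
#'   necrosis)
#' @param duration simulated time, min
#' @param seed integer seed; all stochastic death events derive from it
#' @param pb a [pbpk_parameters()]
#' @param geom a [sinusoid_geometry()]
#' @param zonation a [zonation_profile()]
#' @param n_sub transport sub-steps per macro step (the macro step is
#'   `n_sub` section-transit times, about 0.5 min by default)
#' @param record_maps record lobule concentration snapshots every
#'   `map_interval` minutes (0 disables)
#' @param map_interval snapshot spacing, min
#' @param rtol,atol cell integrator tolerances
#' @return `hepasim_result`: list with `pk` (data.frame of compartment
#'   concentrations over time, mg/L), `viability` (data.frame over time),
#'   `events` (death events), `maps` (optional snapshots), `balance`
#'   (relative mass-balance error over time), and the final `lobule`
#' @export
simulate <- function(regimen, individual, duration = 2000, seed = 1,
                     pb = pbpk_parameters(), geom = sinusoid_geometry(),
                     zonation = zonation_profile(), n_sub = 65L,
                     record_maps = FALSE, map_interval = 60,
                     rtol = 1e-6, atol = 1e-4) {
  stopifnot(duration > 0, inherits(regimen, "dose_regimen"))
  profile <- individual$profile
  if (is.null(profile)) stop("individual$profile is required")
  injury <- individual$injury
  set.seed(as.integer(seed))

  lob <- lobule_model(geom, profile, zonation, injury)
  dt <- n_sub * geom$dt_sub_min
  n_steps <- ceiling(duration / dt)
  scale <- .lobule_scale(pb, geom, lob$n_sinusoids)
  k_gut <- regimen$k_gut

  # y: Qgut, C_adipose, C_wpt, C_ppt, C_liv, C_b, urinary, removed (mg)
  y <- numeric(8)
  dosed <- rep(FALSE, length(regimen$times_min))
  administered <- 0

  n_rec <- n_steps + 1
  pk <- matrix(0, n_rec, 9)
  colnames(pk) <- c("time_min", "gut_mg", "adipose", "wpt", "ppt",
                    "liver", "blood", "urinary_mg", "metabolized_mg")
  viab <- numeric(n_rec)
  bal <- numeric(n_rec)
  viab[1] <- 1
  maps <- list()
  elim_mg_min <- 0
  t <- 0

  for (step in seq_len(n_steps)) {
    # oral boluses due at or before the start of this step
    due <- !dosed & regimen$times_min <= t + 1e-9
    if (any(due)) {
      for (i in which(due)) {
        y[1] <- y[1] + gut_bolus(regimen, i)
        administered <- administered + gut_bolus(regimen, i)
      }
      dosed[due] <- TRUE
    }
    # lobule sees the unbound portal inflow mix at the start of the step
    c_portal <- y[6] + k_gut * y[1] / pb$flows[["liver"]]
    inlet_uM <- geom$fu * .mgL_to_uM(max(c_portal, 0))
    lob <- lobule_step(lob, inlet_uM, dt, rtol = rtol, atol = atol)
    elim_mg_min <- pb$xi * scale * lob$clearance_umol_min *
      .const$mw_apap / 1000
    # PBPK over the macro step with the clearance held constant
    n_pk_sub <- 5L
    h <- dt / n_pk_sub
    for (i in seq_len(n_pk_sub))
      y <- .rk4_step(y, h, function(z) .pbpk_rhs(z, pb, k_gut,
                                                 elim_mg_min))
    t <- t + dt
    pk[step + 1, ] <- c(t, y[1], y[2], y[3], y[4], y[5], y[6], y[7], y[8])
    viab[step + 1] <- lobule_viability(lob)
    body_mg <- y[1] + pb$volumes[["adipose"]] * y[2] +
      pb$volumes[["wpt"]] * y[3] + pb$volumes[["ppt"]] * y[4] +
      pb$volumes[["liver"]] * y[5] + pb$volumes[["blood"]] * y[6] +
      y[7] + y[8]
    bal[step + 1] <- if (administered > 0)
      (body_mg - administered) / administered else 0
    if (record_maps && (t %% map_interval) < dt) {
      maps[[length(maps) + 1]] <- cbind(concentration_map(lob, "NAPQI"),
                                        viability = viab[step + 1])
    }
  }
  pk[1, "time_min"] <- 0
  if (any(abs(bal) > 1e-3))
    warning("whole-body mass balance error exceeded 0.1% of the dose")

  structure(list(
    pk = as.data.frame(pk),
    viability = data.frame(time_min = pk[, "time_min"], viability = viab),
    events = lob$events,
    maps = if (length(maps)) do.call(rbind, maps) else NULL,
    balance = bal,
    lobule = lob,
    seed = seed, duration = duration, regimen = regimen
  ), class = "hepasim_result")
}

#' @export
print.hepasim_result <- function(x, ...) {
  n_ev <- if (is.null(x$events)) 0 else nrow(x$events)
  cat("whole-body simulation:", max(x$pk$time_min), "min; dose",
      paste(x$regimen$doses_mg_kg, collapse = "+"), "mg/kg;",
      "final viability", signif(tail(x$viability$viability, 1), 4),
      "(", n_ev, "death events ); Cmax blood",
      signif(max(x$pk$blood), 4), "mg/L\n")
  invisible(x)
}

#' Summary quantities of a simulation
#' @param result a `hepasim_result`
#' @return list with Cmax (mg/L), Tmax (min), final viability, AUC of the
#'   blood curve (mg/L * min), and time of (near-)complete elimination
#' @export
pk_summary <- function(result) {
  pk <- result$pk
  i_max <- which.max(pk$blood)
  auc <- sum(diff(pk$time_min) *
               (head(pk$blood, -1) + tail(pk$blood, -1)) / 2)
  thresh <- 0.01 * pk$blood[i_max]
  after <- pk$time_min > pk$time_min[i_max] & pk$blood < thresh
  list(cmax_mg_L = pk$blood[i_max], tmax_min = pk$time_min[i_max],
       auc_mg_L_min = auc,
       viability = tail(result$viability$viability, 1),
       t_eliminated_min = if (any(after)) min(pk$time_min[after]) else NA)
}
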