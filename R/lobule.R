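#' Zonation profile of CYP activity along the sinusoid
#'
#' The periportal-to-pericentral oxygen gradient induces three zones with
#' different CYP3A4 activity: zones 1 and 2 are similar and zone 3
#' (pericentral) is about 1.3 times more active.
#'
#' @param boundaries upper boundaries of zones 1 and 2 as fractions of the
#'   sinusoid length (zone 3 ends at 1)
#' @param multipliers CYP3A4 Vmax multiplier per zone
#' @return `zonation_profile` object
#' @export
zonation_profile <- function(boundaries = c(1 / 3, 2 / 3),
                             multipliers = c(1.0, 1.0, 1.3)) {
  stopifnot(length(boundaries) == 2, length(multipliers) == 3,
            all(multipliers > 0), boundaries[1] > 0,
            boundaries[2] > boundaries[1], boundaries[2] < 1)
  structure(list(boundaries = boundaries, multipliers = multipliers),
            class = "zonation_profile")
}

#' Flat (zonation-free) control profile
#' @return `zonation_profile` with all multipliers 1
#' @export
flat_zonation <- function() zonation_profile(multipliers = c(1, 1, 1))

#' CYP3A4 multiplier at a position along the sinusoid
#'
#' @param x_frac position, 0 = portal inlet, 1 = central vein (vectorised)
#' @param zp a [zonation_profile()]
#' @return piecewise-constant multiplier
#' @export
zone_multiplier <- function(x_frac, zp = zonation_profile()) {
  if (any(x_frac < 0 | x_frac > 1)) stop("x_frac must be in [0, 1]")
  zone <- findInterval(x_frac, c(zp$boundaries), left.open = FALSE) + 1L
  zp$multipliers[zone]
}

#' Assemble a liver lobule of parallel sinusoids
#'
#' The lobule is a mean hexagonal unit: `n_sinusoids` identical sinusoids
#' drain blood from the portal triads to the central vein. Identical
#' deterministic dynamics are integrated once and expanded into individual
#' sinusoid copies only when the first stochastic death executes (the
#' expansion is exact, not an approximation).
#'
#' @param geom a [sinusoid_geometry()]
#' @param profile an [enzyme_profile()]
#' @param zonation a [zonation_profile()]
#' @param injury an [injury_parameters()], or `NULL` to disable necrosis
#' @param n_sinusoids sinusoids per lobule
#' @return `lobule_model` object
#' @export
lobule_model <- function(geom = sinusoid_geometry(),
                         profile = enzyme_profile(),
                         zonation = zonation_profile(),
                         injury = NULL, n_sinusoids = 6L) {
  ns <- geom$n_sections
  x_frac <- (seq_len(ns) - 0.5) / ns
  zone <- zone_multiplier(x_frac, zonation)
  lob <- list(
    geom = geom, profile = profile, zonation = zonation, injury = injury,
    n_sinusoids = as.integer(n_sinusoids),
    x_frac = x_frac,
    sin = list(sinusoid_state(geom, profile, zone)),
    collapsed = TRUE,
    cumhaz = matrix(0, 1, ns),
    theta = NULL,       # per-cell survival thresholds, drawn lazily
    triggered = array(FALSE, c(n_sinusoids, ns, geom$cells_per_section)),
    pending = NULL,
    events = NULL,
    time = 0
  )
  class(lob) <- "lobule_model"
  lob
}

#' @export
print.lobule_model <- function(x, ...) {
  tot <- x$n_sinusoids * x$geom$n_sections * x$geom$cells_per_section
  cat("lobule:", x$n_sinusoids, "sinusoids,", tot, "cells; viability",
      signif(lobule_viability(x), 4), "at t =", signif(x$time, 5),
      "min\n")
  invisible(x)
}

#' Fraction of lobule cells alive
#' @param lob a [lobule_model()]
#' @return alive cells / total cells
#' @export
lobule_viability <- function(lob) {
  per_sin <- vapply(lob$sin, function(s) sum(s$n_alive), numeric(1))
  alive <- if (lob$collapsed) per_sin[1] * lob$n_sinusoids else
    sum(per_sin)
  alive / (lob$n_sinusoids * lob$geom$n_sections *
             lob$geom$cells_per_section)
}

# Replicate the single symmetric sinusoid into per-sinusoid copies.
.expand_lobule <- function(lob) {
  if (!lob$collapsed) return(lob)
  lob$sin <- rep(lob$sin[1], lob$n_sinusoids)
  lob$cumhaz <- matrix(rep(lob$cumhaz[1, ], each = lob$n_sinusoids),
                       lob$n_sinusoids, ncol(lob$cumhaz))
  lob$collapsed <- FALSE
  lob
}

#' Advance the lobule by one discrete time step
#'
#' Each sinusoid is advanced with the same inlet concentration (fraction
#' unbound already applied once at the inlet by the caller); the clearance
#' term is the mean of the per-sinusoid elimination rates. If the lobule
#' carries injury parameters, per-cell cumulative hazards are accumulated
#' while the necrosis criterion (H2O2 above the critical value with GSH
#' depleted) holds, cells whose hazard exceeds their survival threshold
#' trigger a death event with a uniform onset delay, and due events are
#' executed (cell frozen, alive count decremented).
#'
#' @param lob a [lobule_model()]
#' @param inlet_conc inlet APAP concentration (uM, unbound) or length-5
#'   vector over bulk species
#' @param dt step length, min
#' @param rtol,atol cell integrator tolerances
#' @return the updated lobule; elements `clearance_umol_min` (mean
#'   elimination rate of this step) and `events` (death events executed so
#'   far)
#' @export
lobule_step <- function(lob, inlet_conc, dt, rtol = 1e-6, atol = 1e-4) {
  stopifnot(inherits(lob, "lobule_model"), dt > 0)
  inj <- lob$injury
  # draw per-cell survival thresholds on first use (one exponential each)
  if (!is.null(inj) && is.null(lob$theta)) {
    n_tot <- lob$n_sinusoids * lob$geom$n_sections *
      lob$geom$cells_per_section
    lob$theta <- array(stats::rexp(n_tot),
                       c(lob$n_sinusoids, lob$geom$n_sections,
                         lob$geom$cells_per_section))
  }
  for (k in seq_along(lob$sin))
    lob$sin[[k]] <- propagate_step(lob$sin[[k]], inlet_conc, dt,
                                   injury = NULL, rtol = rtol, atol = atol)
  lob$time <- lob$sin[[1]]$time
  rates <- vapply(lob$sin, elimination_rate, numeric(1), dt = dt)
  lob$clearance_umol_min <- mean(if (lob$collapsed)
    rep(rates, lob$n_sinusoids) else rates)

  if (!is.null(inj)) {
    w <- positional_weight(lob$x_frac, inj)
    basal <- lob$sin[[1]]$basal_gsh
    for (k in seq_along(lob$sin)) {
      s <- lob$sin[[k]]
      crit <- s$cells["H2O2", ] > inj$h2o2_crit &
        s$cells["GSH", ] < inj$gsh_depletion_fraction * basal &
        s$n_alive > 0
      lob$cumhaz[k, crit] <- lob$cumhaz[k, crit] +
        inj$hazard_scale * w[crit] * dt
    }
    # triggers: cells whose cumulative hazard passed their threshold
    sins <- if (lob$collapsed) seq_len(lob$n_sinusoids) else
      seq_along(lob$sin)
    for (si in sins) {
      hz_row <- if (lob$collapsed) lob$cumhaz[1, ] else lob$cumhaz[si, ]
      for (sec in which(hz_row > 0)) {
        for (slot in seq_len(lob$geom$cells_per_section)) {
          if (lob$triggered[si, sec, slot]) next
          if (hz_row[sec] >= lob$theta[si, sec, slot]) {
            lob$triggered[si, sec, slot] <- TRUE
            delay <- runif(1, inj$delay_min, inj$delay_max)
            ev <- data.frame(sinusoid = si, section = sec, slot = slot,
                             x_frac = lob$x_frac[sec],
                             time_trigger = lob$time,
                             time_exec = lob$time + delay)
            lob$pending <- rbind(lob$pending, ev)
          }
        }
      }
    }
    # execute due deaths
    if (!is.null(lob$pending) && nrow(lob$pending)) {
      due <- lob$pending$time_exec <= lob$time
      if (any(due)) {
        if (lob$collapsed) lob <- .expand_lobule(lob)
        for (i in which(due)) {
          ev <- lob$pending[i, ]
          s <- lob$sin[[ev$sinusoid]]
          if (s$n_alive[ev$section] > 0) {
            s$n_alive[ev$section] <- s$n_alive[ev$section] - 1L
            s$frozen[[ev$section]] <- c(
              s$frozen[[ev$section]],
              list(list(conc = s$cells[, ev$section],
                        t_exec = ev$time_exec)))
            lob$sin[[ev$sinusoid]] <- s
            lob$events <- rbind(lob$events, ev)
          }
        }
        lob$pending <- lob$pending[!due, , drop = FALSE]
      }
    }
  }
  lob
}

#' Per-cell viability table of the lobule
#'
#' @param lob a [lobule_model()]
#' @return list with `map`, a data.frame keyed by
#'   (sinusoid, section, slot, x_frac) with an `alive` flag, and
#'   `viability`, the summary fraction
#' @export
viability_map <- function(lob) {
  g <- lob$geom
  grid <- expand.grid(slot = seq_len(g$cells_per_section),
                      section = seq_len(g$n_sections),
                      sinusoid = seq_len(lob$n_sinusoids))
  grid <- grid[, c("sinusoid", "section", "slot")]
  grid$x_frac <- lob$x_frac[grid$section]
  n_alive <- vapply(seq_len(nrow(grid)), function(i) {
    k <- if (lob$collapsed) 1L else grid$sinusoid[i]
    lob$sin[[k]]$n_alive[grid$section[i]]
  }, numeric(1))
  grid$alive <- grid$slot <= n_alive
  list(map = grid, viability = mean(grid$alive))
}

#' Spatial concentration table of the lobule
#'
#' Bulk and live-cell concentrations of one species per sinusoid section,
#' in the layout of the spatial-distribution outputs (time, sinusoid,
#' section, normalised position, bulk and cellular concentration).
#'
#' @param lob a [lobule_model()]
#' @param species one of the species names; bulk reports the sinusoidal
#'   bulk concentration where the species has an extracellular slot
#' @return data.frame `time_min, sinusoid, section, x_frac, species,
#'   bulk_uM, cell_uM`
#' @export
concentration_map <- function(lob, species = "NAPQI") {
  bulk_names <- rownames(lob$sin[[1]]$bulk)
  cell_names <- rownames(lob$sin[[1]]$cells)
  cell_sp <- if (species == "APAP") "APAP_cyt" else species
  out <- list()
  for (si in seq_len(lob$n_sinusoids)) {
    k <- if (lob$collapsed) 1L else si
    s <- lob$sin[[k]]
    out[[si]] <- data.frame(
      time_min = lob$time, sinusoid = si,
      section = seq_len(lob$geom$n_sections), x_frac = lob$x_frac,
      species = species,
      bulk_uM = if (species %in% bulk_names)
        as.numeric(s$bulk[species, ]) else NA_real_,
      cell_uM = if (cell_sp %in% cell_names)
        as.numeric(s$cells[cell_sp, ]) else NA_real_)
  }
  do.call(rbind, out)
}
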