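#' Sinusoid geometry and transport constants
#'
#' Physical description of one sinusoid: a cylindrical tube of radius
#' `r_m` lined by `n_sections` sections of `cells_per_section` hepatocytes
#' of size `l_h_m`, carrying blood at the near-wall suspension velocity
#' `u_x_m_s` (Fahraeus-corrected; the red-cell velocity is about twice as
#' large). The dispersion coefficient defaults to the Stokes-Einstein value
#' for APAP. The fraction unbound `fu` is applied once at the portal inlet.
#'
#' @param n_sections hepatocyte sections along the sinusoid
#' @param cells_per_section hepatocytes per section
#' @param l_h_m hepatocyte size, m
#' @param r_m sinusoid radius, m
#' @param u_x_m_s suspension velocity, m/s
#' @param d_m2_s dispersion coefficient, m^2/s
#' @param fu fraction unbound of APAP in blood
#' @return `sinusoid_geometry` object with derived volumes (litres)
#' @export
sinusoid_geometry <- function(n_sections = 16L, cells_per_section = 4L,
                              l_h_m = 23e-6, r_m = 5e-6,
                              u_x_m_s = 0.05e-3,
                              d_m2_s = diffusion_coefficient(),
                              fu = 0.75) {
  stopifnot(n_sections >= 1, cells_per_section >= 1, l_h_m > 0, r_m > 0,
            u_x_m_s > 0, d_m2_s >= 0, fu > 0, fu <= 1)
  g <- list(
    n_sections = as.integer(n_sections),
    cells_per_section = as.integer(cells_per_section),
    l_h_m = l_h_m, r_m = r_m, u_x_m_s = u_x_m_s, d_m2_s = d_m2_s, fu = fu,
    length_m = n_sections * l_h_m,
    v_bulk_L = pi * r_m^2 * l_h_m * 1e3,   # bulk volume of one section
    v_cell_L = l_h_m^3 * 1e3,              # one hepatocyte
    dt_sub_min = l_h_m / u_x_m_s / 60      # one-section transit time
  )
  class(g) <- "sinusoid_geometry"
  g
}

#' @export
print.sinusoid_geometry <- function(x, ...) {
  cat("sinusoid:", x$n_sections, "sections x", x$cells_per_section,
      "cells; L =", signif(x$length_m * 1e6, 4), "um; U_x =",
      x$u_x_m_s * 1e3, "mm/s; D =", signif(x$d_m2_s, 4), "m2/s; fu =",
      x$fu, "\n")
  invisible(x)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB * T / (f * pi * eta * R_g)` for a spherical molecule with sticky
#' boundary conditions (`f = 6`) in a low-Reynolds-number liquid. With the
#' blood viscosity 3e-3 Pa s and the APAP radius of gyration 2.99 Angstrom
#' this gives about 2.22e-10 m^2/s.
#'
#' @param T_K temperature, K
#' @param eta_Pa_s dynamic viscosity, Pa s
#' @param R_g_m radius of gyration, m
#' @param f boundary-condition factor (6 = sticky/sphere)
#' @return diffusion coefficient, m^2/s
#' @examples
#' diffusion_coefficient()  # ~2.22e-10 m^2/s for APAP in blood
#' @export
diffusion_coefficient <- function(T_K = 273, eta_Pa_s = 3e-3,
                                  R_g_m = 2.99e-10, f = 6) {
  if (any(c(T_K, eta_Pa_s, R_g_m, f) <= 0))
    stop("all Stokes-Einstein inputs must be > 0")
  .const$k_boltzmann * T_K / (f * pi * eta_Pa_s * R_g_m)
}

#' Analytic dispersive plume along the sinusoid
#'
#' Green's-function solution of the advection-dispersion equation for a
#' bolus of `Q_umol` released at `x = 0`, `t = 0` in a tube of radius `r`:
#' `c(t, x) = Q / (pi r^2) / sqrt(4 pi D t) * exp(-(x - U t)^2 / (4 D t))`.
#'
#' @param Q_umol released amount, umol
#' @param t_s time since release, s (> 0)
#' @param x_m position along the tube, m (vectorised)
#' @param geom a [sinusoid_geometry()]
#' @return concentration in uM
#' @export
plume_concentration <- function(Q_umol, t_s, x_m,
                                geom = sinusoid_geometry()) {
  if (t_s <= 0) stop("t must be > 0")
  area_m2 <- pi * geom$r_m^2
  sig2 <- 2 * geom$d_m2_s * t_s                   # variance, m^2
  dens <- exp(-(x_m - geom$u_x_m_s * t_s)^2 / (2 * sig2)) /
    sqrt(2 * pi * sig2)                           # 1/m, integrates to 1
  amount_per_m <- Q_umol * dens                   # umol/m
  amount_per_m / (area_m2 * 1e3)                  # umol/L = uM
}

#' Discrete dispersion kernel over one transport sub-step
#'
#' The bulk propagator is split into an exact one-section advective shift
#' (the sub-step equals one section transit, `l_h / U_x`) and a dispersion
#' kernel `expm(theta * L)` where `L` is the zero-flux (reflecting)
#' discrete Laplacian on the section grid and
#' `theta = D dt / l_h^2`. The matrix exponential is evaluated in the
#' analytic cosine eigenbasis of `L`, so composing `n` single-step kernels
#' is exactly the kernel for `n` steps (semigroup property) and total mass
#' is conserved to machine precision. As `D -> 0` the kernel degenerates to
#' the identity and transport becomes pure plug flow.
#'
#' @param geom a [sinusoid_geometry()]
#' @param dt_s sub-step length in seconds (default one section transit)
#' @param n number of grid sections
#' @return `n x n` dispersion matrix (applied to section amounts)
#' @export
dispersion_kernel <- function(geom = sinusoid_geometry(),
                              dt_s = geom$l_h_m / geom$u_x_m_s,
                              n = geom$n_sections) {
  theta <- geom$d_m2_s * dt_s / geom$l_h_m^2
  k <- 0:(n - 1)
  lambda <- -4 * sin(k * pi / (2 * n))^2
  # orthonormal DCT-II basis: V[i,j] = w_j cos((i - 1/2) (j-1) pi / n)
  i <- matrix(seq_len(n) - 0.5, n, n)
  j <- matrix(k, n, n, byrow = TRUE)
  V <- cos(i * j * pi / n)
  w <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  V <- sweep(V, 2, w, `*`)
  V %*% (exp(theta * lambda) * t(V))
}

#' Initialise the state of one sinusoid
#'
#' @param geom a [sinusoid_geometry()]
#' @param profile an [enzyme_profile()]
#' @param zone numeric vector of CYP3A4 zonation multipliers per section
#'   (default all 1)
#' @return `sinusoid_state`: bulk concentrations (5 species x sections:
#'   APAP, APAPG, APAPS, APAPGS, NAPQI), the shared live-cell state per
#'   section, alive counts, frozen dead-cell states, cumulative eliminated
#'   APAP `E` (umol) and cumulative outlet amounts (umol)
#' @export
sinusoid_state <- function(geom = sinusoid_geometry(),
                           profile = enzyme_profile(),
                           zone = rep(1, geom$n_sections)) {
  ns <- geom$n_sections
  stopifnot(length(zone) == ns, all(zone > 0))
  c0 <- cell_initial_state(profile)
  s <- list(
    geom = geom,
    profile = profile,
    zone = as.numeric(zone),
    bulk = matrix(0, 5, ns,
                  dimnames = list(c("APAP", "APAPG", "APAPS", "APAPGS",
                                    "NAPQI"), NULL)),
    cells = matrix(c0[1:12], 12, ns,
                   dimnames = list(.hepasim_species()[1:12], NULL)),
    n_alive = rep(geom$cells_per_section, ns),
    frozen = vector("list", ns),   # list of dead-cell state snapshots
    basal_gsh = basal_gsh(profile),
    E = 0,
    outlet = setNames(numeric(5), c("APAP", "APAPG", "APAPS", "APAPGS",
                                    "NAPQI")),
    last_dE = 0,
    time = 0
  )
  class(s) <- "sinusoid_state"
  s
}

#' @export
print.sinusoid_state <- function(x, ...) {
  cat("sinusoid at t =", signif(x$time, 5), "min;",
      sum(x$n_alive), "/", x$geom$n_sections * x$geom$cells_per_section,
      "cells alive; E =", signif(x$E, 5), "umol\n")
  invisible(x)
}

#' Advance one sinusoid by one discrete time step
#'
#' Operator-split step: (1) bulk advection-dispersion of each species over
#' `n_sub` sub-steps using the discrete kernel (mass exactly redistributed
#' between sections and the outlet); (2) local exchange between each
#' section's bulk and its resident live cells (passive relaxation plus the
#' saturable APAP carrier) with the cells' metabolism integrated over the
#' step; (3) optional stochastic death checks per cell; (4) the eliminated
#' amount `E` incremented by the net APAP removed from the bulk by cells.
#'
#' @param s a [sinusoid_state()]
#' @param inlet_conc inlet (portal) concentrations, uM: either a single
#'   APAP value or a length-5 vector over the bulk species. The fraction
#'   unbound must already be applied by the caller.
#' @param dt step length, min (an integer number of transport sub-steps;
#'   rounded to the nearest)
#' @param injury an [injury_parameters()] to enable death checks, or
#'   `NULL` to disable them
#' @param rtol,atol cell integrator tolerances
#' @return the updated state; elements `last_dE` (umol eliminated in this
#'   step), `events` (data.frame of death events in this step)
#' @export
propagate_step <- function(s, inlet_conc, dt, injury = NULL,
                           rtol = 1e-6, atol = 1e-4) {
  stopifnot(inherits(s, "sinusoid_state"), dt > 0)
  if (length(inlet_conc) == 1) inlet_conc <- c(inlet_conc, 0, 0, 0, 0)
  if (any(inlet_conc < 0)) stop("negative inflow")
  g <- s$geom
  n_sub <- max(1L, as.integer(round(dt / g$dt_sub_min)))
  kd <- .kernel_cache(g)
  res <- .sinusoid_step_cpp(
    s$bulk, s$cells, as.integer(s$n_alive), s$zone,
    .profile_vector(s$profile), kd, as.numeric(inlet_conc),
    n_sub, g$dt_sub_min, g$v_cell_L / g$v_bulk_L, g$v_bulk_L, g$v_cell_L,
    rtol, atol)
  # mass balance audit per bulk species:
  # init + inlet + export_from_cells = final + outlet + moved_into_cells
  lhs <- rowSums(s$bulk) * g$v_bulk_L + res$inlet_amount + res$exported
  rhs <- rowSums(res$bulk) * g$v_bulk_L + res$outlet + res$transferred
  scale_amt <- pmax(lhs, g$v_bulk_L * 1e-6)
  if (any(abs(lhs - rhs) / scale_amt > 1e-6))
    warning("sinusoid mass balance violated beyond tolerance")
  s$bulk <- res$bulk
  s$cells <- res$cells
  s$E <- s$E + res$e_apap
  s$last_dE <- res$e_apap
  s$outlet <- s$outlet + setNames(as.numeric(res$outlet), names(s$outlet))
  s$time <- s$time + n_sub * g$dt_sub_min
  s$events <- NULL
  if (!is.null(injury)) {
    ev <- list()
    x_frac <- (seq_len(g$n_sections) - 0.5) / g$n_sections
    for (sec in seq_len(g$n_sections)) {
      n_al <- s$n_alive[sec]
      if (n_al <= 0) next
      cellvec <- setNames(c(s$cells[, sec], numeric(5)),
                          .hepasim_species())
      for (slot in seq_len(n_al)) {
        ev_i <- death_check(cellvec, x_frac[sec], injury,
                            n_sub * g$dt_sub_min, t = s$time,
                            basal = s$basal_gsh)
        if (!is.null(ev_i)) {
          ev_i$section <- sec
          ev[[length(ev) + 1]] <- ev_i
          s$n_alive[sec] <- s$n_alive[sec] - 1L
          s$frozen[[sec]] <- c(s$frozen[[sec]],
                               list(list(conc = s$cells[, sec],
                                         t_exec = ev_i$time_exec)))
        }
      }
    }
    if (length(ev)) s$events <- do.call(rbind, ev)
  }
  s
}

# cache the dispersion kernel per geometry (it is fixed within a run)
.kernel_env <- new.env(parent = emptyenv())
.kernel_cache <- function(g) {
  key <- paste0(g$n_sections, "_", signif(g$d_m2_s, 12), "_",
                signif(g$dt_sub_min, 12))
  if (is.null(.kernel_env[[key]]))
    .kernel_env[[key]] <- dispersion_kernel(g)
  .kernel_env[[key]]
}

#' Elimination rate of the last step
#'
#' `dE/dt` of the most recent [propagate_step()]: the net rate at which
#' the sinusoid removed APAP from the bulk, umol/min. The whole-body
#' coupling consumes the mean of this quantity over the six sinusoids.
#'
#' @param s a [sinusoid_state()]
#' @param dt the step length used, min
#' @return umol/min
#' @export
elimination_rate <- function(s, dt) {
  stopifnot(inherits(s, "sinusoid_state"), dt > 0)
  s$last_dE / dt
}
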