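#' Necrosis model parameters
#'
#' Cell death is triggered when intracellular H2O2 exceeds a critical
#' concentration while glutathione is depleted (below a fraction of its
#' basal level). When the criterion holds, death occurs stochastically with
#' a per-minute hazard that increases toward the central vein (pericentral
#' cells, which are hypoxic, are the most sensitive); an executed death is
#' preceded by a short uniform random delay.
#'
#' @param h2o2_crit critical intracellular H2O2, uM (default 4000; normally
#'   set by [calibrate_injury()] from the in-vitro LC50 exposure)
#' @param gsh_depletion_fraction fraction of basal GSH below which
#'   glutathione counts as consumed
#' @param delay_min,delay_max bounds of the uniform onset delay, min
#' @param sensitivity_floor lower bound of the positional hazard weight
#'   (weight at the portal inlet)
#' @param hazard_scale base hazard (1/min) when the criterion is met at the
#'   central vein
#' @return `injury_parameters` object
#' @export
injury_parameters <- function(h2o2_crit = 4000,
                              gsh_depletion_fraction = 0.1,
                              delay_min = 0, delay_max = 1,
                              sensitivity_floor = 0.05,
                              hazard_scale = 5) {
  if (h2o2_crit <= 0) stop("h2o2_crit must be > 0")
  if (gsh_depletion_fraction < 0 || gsh_depletion_fraction >= 1)
    stop("gsh_depletion_fraction must be in [0, 1)")
  if (delay_min < 0 || delay_max < delay_min)
    stop("need 0 <= delay_min <= delay_max")
  if (sensitivity_floor <= 0 || sensitivity_floor > 1)
    stop("sensitivity_floor must be in (0, 1]")
  if (hazard_scale < 0) stop("hazard_scale must be >= 0")
  structure(list(h2o2_crit = h2o2_crit,
                 gsh_depletion_fraction = gsh_depletion_fraction,
                 delay_min = delay_min, delay_max = delay_max,
                 sensitivity_floor = sensitivity_floor,
                 hazard_scale = hazard_scale),
            class = "injury_parameters")
}

#' @export
print.injury_parameters <- function(x, ...) {
  cat("injury parameters: H2O2_crit =", x$h2o2_crit,
      "uM; GSH depleted below", x$gsh_depletion_fraction, "x basal;",
      "delay U[", x$delay_min, ",", x$delay_max, "] min\n")
  invisible(x)
}

#' Positional sensitivity weight along the sinusoid
#'
#' The probability of necrosis is inversely proportional to the distance to
#' the central vein: `weight = min(1, floor / (1 - x + eps))`, anchored to
#' 1 at the central vein (`x = 1`) and non-decreasing in `x`.
#'
#' @param x_frac position along the sinusoid, 0 = portal inlet,
#'   1 = central vein
#' @param params an [injury_parameters()]
#' @return weight in (0, 1]
#' @export
positional_weight <- function(x_frac, params = injury_parameters()) {
  if (any(x_frac < 0 | x_frac > 1)) stop("x_frac must be in [0, 1]")
  eps <- 1e-9
  pmin(1, params$sensitivity_floor / (1 - x_frac + eps))
}

#' Stochastic death check for one live cell over one time step
#'
#' If intracellular H2O2 exceeds the critical value while GSH is below the
#' depletion fraction of its basal level, the cell dies within the step
#' with probability `1 - exp(-hazard_scale * weight(x) * dt)`. A death
#' draws a uniform onset delay giving the execution time.
#'
#' @param cell named species vector of the (live) cell, uM
#' @param x_frac position along the sinusoid
#' @param params an [injury_parameters()]
#' @param dt step length, min
#' @param t current time, min (trigger time stamp)
#' @param basal basal GSH of this cell, uM
#' @return `NULL` (no event) or a one-row data.frame with
#'   `time_trigger` and `time_exec`
#' @export
death_check <- function(cell, x_frac, params, dt, t = 0,
                        basal = basal_gsh()) {
  if (dt <= 0) stop("dt must be > 0")
  crit <- cell[["H2O2"]] > params$h2o2_crit &&
    cell[["GSH"]] < params$gsh_depletion_fraction * basal
  if (!crit) return(NULL)
  w <- positional_weight(x_frac, params)
  p_die <- 1 - exp(-params$hazard_scale * w * dt)
  if (runif(1) >= p_die) return(NULL)
  delay <- runif(1, params$delay_min, params$delay_max)
  data.frame(time_trigger = t, time_exec = t + delay)
}

#' Freeze a cell at its death execution time
#'
#' Marks the cell dead; all metabolic and transport fluxes are zero from
#' the execution time onward and the intracellular concentrations stay at
#' their values at that time.
#'
#' @param cell a list with fields `conc` (species vector), `alive`
#'   (logical) and `t_death` (NA while alive)
#' @param t_exec execution time, min
#' @return the frozen cell
#' @export
apply_death <- function(cell, t_exec) {
  if (!isTRUE(cell$alive)) stop("apply_death called on a dead cell")
  cell$alive <- FALSE
  cell$t_death <- t_exec
  cell
}
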