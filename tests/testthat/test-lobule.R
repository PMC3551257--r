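test_that("zonation multipliers follow the three-zone layout", {
  zp <- zonation_profile()
  expect_equal(zone_multiplier(0.9, zp), 1.3)
  expect_equal(zone_multiplier(0.1, zp), zone_multiplier(0.5, zp))
  expect_equal(zone_multiplier(0.1, zp), 1.0)
  expect_equal(zone_multiplier(c(0, 1 / 3, 2 / 3, 1), zp),
               c(1, 1, 1.3, 1.3))
  # flat profile: zonation-free control
  expect_equal(zone_multiplier(seq(0, 1, 0.25), flat_zonation()),
               rep(1, 5))
  expect_error(zone_multiplier(-0.1, zp), "x_frac")
})

test_that("the lobule is a pure aggregator of identical sinusoids", {
  g <- test_geometry()
  lob <- lobule_model(g, enzyme_profile(), zonation_profile())
  dt <- 65 * g$dt_sub_min
  lob <- lobule_step(lob, 800, dt)
  # with deaths disabled the six sinusoids stay collapsed onto one, and
  # the clearance equals any single sinusoid's elimination rate
  expect_true(lob$collapsed)
  single <- sinusoid_state(g, enzyme_profile(),
                           zone_multiplier(lob$x_frac))
  single <- propagate_step(single, 800, dt)
  expect_equal(lob$clearance_umol_min, elimination_rate(single, dt),
               tolerance = 1e-12)
  expect_equal(lobule_viability(lob), 1)
})

test_that("viability map starts full and stays consistent with events", {
  g <- test_geometry()
  lob <- lobule_model(g, enzyme_profile(), zonation_profile(),
                      injury = injury_parameters())
  vm <- viability_map(lob)
  expect_equal(vm$viability, 1)
  expect_equal(nrow(vm$map), 6 * 16 * 4)
  # force deaths by hand and check the bookkeeping identity
  lob2 <- hepasim:::.expand_lobule(lob)
  lob2$sin[[3]]$n_alive[16] <- 2L
  vm2 <- viability_map(lob2)
  expect_equal(sum(!vm2$map$alive), 2)
  expect_equal(vm2$viability, 1 - 2 / 384)
})

test_that("zonation increases clearance at sub-saturating inflow", {
  g <- test_geometry()
  dt <- 65 * g$dt_sub_min
  run <- function(zp) {
    lob <- lobule_model(g, enzyme_profile(), zp)
    for (i in 1:12) lob <- lobule_step(lob, 50, dt)
    lob$clearance_umol_min
  }
  expect_gt(run(zonation_profile()), run(flat_zonation()))
})

test_that("all cells dead means zero clearance", {
  g <- test_geometry()
  lob <- lobule_model(g, enzyme_profile(), zonation_profile())
  lob$sin[[1]]$n_alive[] <- 0L
  dt <- 65 * g$dt_sub_min
  lob <- lobule_step(lob, 500, dt)
  expect_equal(lob$clearance_umol_min, 0)
  expect_equal(lobule_viability(lob), 0)
})

test_that("toxic inflow kills pericentral cells first", {
  g <- test_geometry()
  cal <- calibrate_injury(4000)
  lob <- lobule_model(g, cal$profile, zonation_profile(),
                      injury = cal$injury)
  dt <- 65 * g$dt_sub_min
  set.seed(5)
  # sustained high unbound inflow close to the in-vitro LC50
  for (i in seq_len(ceiling(900 / dt))) {
    lob <- lobule_step(lob, 3600, dt)
    if (!is.null(lob$events) && nrow(lob$events) >= 20) break
  }
  expect_false(is.null(lob$events))
  expect_gt(mean(lob$events$x_frac), 0.5)
  # mean NAPQI in zone 3 exceeds zone 1 (toxic metabolite accumulates
  # pericentrally)
  cm <- concentration_map(lob, "NAPQI")
  z3 <- mean(cm$cell_uM[cm$x_frac > 2 / 3])
  z1 <- mean(cm$cell_uM[cm$x_frac < 1 / 3])
  expect_gt(z3, z1)
  # viability equals 1 minus executed deaths over total cells
  expect_equal(lobule_viability(lob),
               1 - nrow(lob$events) / 384)
})
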