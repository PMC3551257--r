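test_that("LC50 interpolation recovers knots and log-midpoints", {
  curve <- data.frame(concentration_uM = c(1000, 4000, 16000),
                      viability = c(1, 0.5, 0))
  expect_equal(estimate_lc50(curve), 4000)
  # interpolation independent of row order
  expect_equal(estimate_lc50(curve[c(3, 1, 2), ]), 4000)
  # a step from 1 to 0 between adjacent points returns the log-midpoint
  step <- data.frame(concentration_uM = c(2000, 8000),
                     viability = c(1, 0))
  expect_equal(estimate_lc50(step), sqrt(2000 * 8000))
  flat <- data.frame(concentration_uM = c(10, 100),
                     viability = c(0.9, 0.8))
  expect_error(estimate_lc50(flat), "bracket")
})

test_that("chi-square statistic has its closed-form properties", {
  a <- sin(1:50)
  expect_equal(chi_square(a, a, 1), 0)
  # constant offset of k*sd per point gives chi^2 = k^2
  expect_equal(chi_square(a, a + 3 * 0.5, 0.5), 9)
  expect_error(chi_square(a, a[-1], 1), "grid")
})

test_that("injury calibration anchors the threshold monotonically", {
  cal <- calibrate_injury(4000)
  expect_equal(cal$injury$h2o2_crit, 4000, tolerance = 1e-3)
  expect_equal(cal$peak_h2o2, cal$injury$h2o2_crit)
  # the nominal cell's GSH is depleted at the calibration exposure
  tr <- simulate_cell(cell_initial_state(cal$profile), cal$profile,
                      4000, 720)
  expect_lt(min(tr$states[, "GSH"]), 0.1 * basal_gsh(cal$profile))
  # doubling the target exposure weakly increases the raw peak H2O2
  raw1 <- calibrate_injury(4000, rescale = FALSE)
  raw2 <- calibrate_injury(8000, rescale = FALSE)
  expect_gte(raw2$peak_h2o2, raw1$peak_h2o2)
})

test_that("in-vitro viability is 1 unexposed and decreases with dose", {
  cal <- calibrate_injury(4000)
  setup <- in_vitro_setup(n_cells = 60,
                          concentrations = c(0, 1000, 4000, 16000),
                          seed = 3)
  curve <- simulate_in_vitro(setup, cal$profile, cal$injury)
  expect_equal(curve$viability[curve$concentration_uM == 0], 1)
  expect_true(all(diff(curve$viability) <= 0.05))  # monotone up to noise
})

test_that("well-stirred reference matches the lobule at sub-toxic dose", {
  profile <- enzyme_profile()
  dose <- 100  # sub-toxic
  res <- simulate(dose_regimen(dose), list(profile = profile),
                  duration = 600, seed = 1)
  ref <- reference_pk(dose, profile, duration = 600, out_dt = 10)
  on_grid <- approx(res$pk$time_min, res$pk$blood, ref$time_min)$y
  # pointwise agreement within 15% of the curve maximum
  expect_lt(max(abs(on_grid - ref$blood)) / max(ref$blood), 0.15)
  # reduced chi-square against a 5%-of-peak scale is small
  expect_lt(chi_square(on_grid, ref$blood, 0.05 * max(ref$blood)), 2)
})

test_that("dose zero in a scan yields exactly full viability", {
  tab <- dose_scan(0, list(profile = enzyme_profile(),
                           injury = injury_parameters()), seeds = 1)
  expect_equal(tab$table$viability_mean, 1)
  expect_true(is.na(tab$threshold_dose))
})
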