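test_that("gut absorption is first order with the stated constants", {
  reg <- dose_regimen(393, weight_kg = 73)
  # 393 mg/kg x 73 kg x 0.9 enters the gut
  expect_equal(gut_bolus(reg), 0.9 * 73 * 393)
  expect_equal(gut_bolus(dose_regimen(0)), 0)
  # analytic decay: half-life ln(2)/0.025 ~ 27.7 min
  q0 <- gut_bolus(reg)
  t_half <- log(2) / reg$k_gut
  q <- q0
  h <- 0.01
  for (i in seq_len(round(t_half / h)))
    q <- q + h * gut_rhs(q, reg)  # Euler at fine step
  expect_equal(q, q0 / 2, tolerance = 1e-3)
})

test_that("flow-limited compartments equilibrate at C_i = C_b * PC", {
  expect_equal(compartment_rhs(c_i = 0.774 * 10, c_b = 10, flow = 3.5,
                               volume = 5.68, pc = 0.774), 0)
  # initial uptake rate F C_b / V from an empty compartment
  expect_equal(compartment_rhs(0, 10, 3.5, 5.68, 0.774), 3.5 * 10 / 5.68)
})

test_that("whole-body defaults reproduce the physiological table", {
  pb <- pbpk_parameters()
  expect_equal(unname(pb$flows[c("adipose", "liver", "wpt", "ppt",
                                 "blood")]),
               c(0.56, 1.3, 3.5, 1.63, 6.4))
  expect_equal(unname(pb$volumes[c("adipose", "liver", "wpt", "ppt",
                                   "blood", "plasma")]),
               c(28.0, 1.82, 5.68, 35, 5.7, 3.4))
  expect_equal(unname(pb$partition[c("adipose", "liver", "wpt", "ppt",
                                     "blood", "plasma")]),
               c(0.25, 0.774, 0.774, 0.66, 0.774, 0.774))
  expect_equal(pb$urinary_cl, 0.016)
  expect_equal(pb$xi, 0.75)
})

test_that("flow equilibrium is a stationary state of the PBPK core", {
  pb <- pbpk_parameters(urinary_cl = 0)
  cb <- 5
  y <- c(0, cb * pb$partition[["adipose"]], cb * pb$partition[["wpt"]],
         cb * pb$partition[["ppt"]], cb * pb$partition[["liver"]], cb,
         0, 0)
  d <- hepasim:::.pbpk_rhs(y, pb, k_gut = 0.025, liver_elim_mg_min = 0)
  expect_lt(max(abs(d)), 1e-12)
})

test_that("zero dose stays identically zero with full viability", {
  res <- simulate(dose_regimen(0), list(profile = enzyme_profile(),
                                        injury = injury_parameters()),
                  duration = 30, seed = 1)
  expect_equal(max(abs(res$pk$blood)), 0)
  expect_equal(max(abs(res$pk$liver)), 0)
  expect_true(all(res$viability$viability == 1))
})

test_that("short runs hold mass balance and a unimodal blood curve", {
  res <- simulate(dose_regimen(100), list(profile = enzyme_profile()),
                  duration = 240, seed = 1)
  expect_lt(max(abs(res$balance)), 1e-3)
  b <- res$pk$blood
  i_max <- which.max(b)
  expect_true(all(diff(b[1:i_max]) >= -1e-12))
  expect_true(all(diff(b[i_max:length(b)]) <= 1e-12))
  # conservative organ exchange: what left the gut is in the body,
  # urine, or metabolised
  last <- nrow(res$pk)
  pb <- pbpk_parameters()
  body <- res$pk$gut_mg[last] +
    sum(unlist(res$pk[last, c("adipose", "wpt", "ppt", "liver",
                              "blood")]) *
          pb$volumes[c("adipose", "wpt", "ppt", "liver", "blood")]) +
    res$pk$urinary_mg[last] + res$pk$metabolized_mg[last]
  expect_equal(body, gut_bolus(dose_regimen(100)), tolerance = 1e-3)
})

test_that("Cmax is dose-linear in the sub-saturation regime", {
  ind <- list(profile = enzyme_profile())
  r1 <- simulate(dose_regimen(2), ind, duration = 300, seed = 1)
  r2 <- simulate(dose_regimen(1), ind, duration = 300, seed = 1)
  expect_equal(max(r1$pk$blood) / max(r2$pk$blood), 2, tolerance = 0.02)
})

test_that("identical seeds give bit-identical simulations", {
  cal <- calibrate_injury(4000)
  ind <- list(profile = cal$profile, injury = cal$injury)
  a <- simulate(dose_regimen(360), ind, duration = 150, seed = 9)
  b <- simulate(dose_regimen(360), ind, duration = 150, seed = 9)
  expect_identical(a$pk, b$pk)
  expect_identical(a$viability, b$viability)
  expect_identical(a$events, b$events)
})

test_that("killing the lobule weakly increases the plasma burden", {
  ind_alive <- list(profile = enzyme_profile())
  res_a <- simulate(dose_regimen(100), ind_alive, duration = 300,
                    seed = 1)
  # same run with every hepatocyte dead from the start
  dead_geom <- sinusoid_geometry()
  res_d <- local({
    r <- simulate(dose_regimen(100),
                  list(profile = enzyme_profile(vmax_ugt = 0,
                                                vmax_sult = 0,
                                                vmax_cyp3a4 = 0,
                                                vmax_cyp2e1 = 0,
                                                vmax_cyp_minor = 0,
                                                vmax_uptake = 0,
                                                p_apap = 0)),
                  duration = 300, seed = 1)
    r
  })
  auc <- function(r) sum(diff(r$pk$time_min) *
                           (head(r$pk$blood, -1) +
                              tail(r$pk$blood, -1)) / 2)
  expect_gte(auc(res_d), auc(res_a) - 1e-9)
})
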