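test_that("Stokes-Einstein relation reproduces the APAP coefficient", {
  # eta = 3e-3 Pa s, Rg = 2.99 A, f = 6, T = 273 K -> 2.22e-10 m^2/s
  D <- diffusion_coefficient(273, 3e-3, 2.99e-10, 6)
  expect_equal(D, 2.22e-10, tolerance = 0.01)
  # D proportional to 1/eta
  expect_equal(diffusion_coefficient(eta_Pa_s = 6e-3), D / 2,
               tolerance = 1e-12)
  # hand-evaluated Stokes-Einstein value as oracle
  by_hand <- 1.380649e-23 * 273 / (6 * pi * 3e-3 * 2.99e-10)
  expect_equal(D, by_hand)
  expect_error(diffusion_coefficient(T_K = -1), "> 0")
})

test_that("the analytic plume conserves mass and advects its peak", {
  g <- test_geometry()
  Q <- 1e-9
  for (t_s in c(0.5, 1, 4)) {
    area_L_per_m <- pi * g$r_m^2 * 1e3
    mass <- integrate(function(x) plume_concentration(Q, t_s, x, g) *
                        area_L_per_m,
                      g$u_x_m_s * t_s - 3e-4, g$u_x_m_s * t_s + 3e-4,
                      rel.tol = 1e-12, abs.tol = 0)$value
    expect_lt(abs(mass - Q) / Q, 1e-9)
  }
  # peak at x = U t: 50 um after 1 s at 0.05 mm/s
  x <- seq(0, 2e-4, by = 1e-7)
  c1 <- plume_concentration(Q, 1, x, g)
  expect_equal(x[which.max(c1)], 50e-6, tolerance = 1e-2)
  # peak height against the closed form
  peak <- Q / (pi * g$r_m^2) / sqrt(4 * pi * g$d_m2_s * 1) / 1e3
  expect_equal(max(c1), peak, tolerance = 1e-4)
  expect_error(plume_concentration(Q, 0, 0, g), "> 0")
})

test_that("discrete kernel is conservative with exact semigroup", {
  g <- test_geometry()
  K1 <- dispersion_kernel(g)
  expect_lt(max(abs(colSums(K1) - 1)), 1e-12)
  # n small steps equal one n-fold step (interior pulse)
  K4 <- dispersion_kernel(g, dt_s = 4 * g$l_h_m / g$u_x_m_s)
  pulse <- numeric(g$n_sections); pulse[8] <- 1
  stepped <- K1 %*% (K1 %*% (K1 %*% (K1 %*% pulse)))
  expect_lt(max(abs(stepped - K4 %*% pulse)), 1e-6)
  # D -> 0 degenerates to the identity (advection is a pure shift)
  g0 <- test_geometry(d_m2_s = 0)
  expect_equal(dispersion_kernel(g0), diag(g0$n_sections),
               tolerance = 1e-12)
})

test_that("discrete kernel converges to the analytic plume", {
  # a long fine grid vs the Green's function after many sub-steps
  g <- sinusoid_geometry(n_sections = 400L, l_h_m = 2e-6)
  K <- dispersion_kernel(g, dt_s = g$l_h_m / g$u_x_m_s)
  n_steps <- 150
  m <- numeric(400); m[50] <- 1
  for (i in seq_len(n_steps)) {
    m <- K %*% m
    m <- c(0, m[-400])  # advective shift by one bin
  }
  t_s <- n_steps * g$l_h_m / g$u_x_m_s
  x <- (seq_len(400) - 50) * g$l_h_m
  analytic <- plume_concentration(1e-9, t_s, x, g)
  numeric_prof <- as.numeric(m) * 1e-9 / (pi * g$r_m^2 * g$l_h_m * 1e3)
  expect_lt(max(abs(numeric_prof - analytic)) / max(analytic), 0.02)
})

test_that("pure transport delivers the inlet to the outlet unchanged", {
  g <- test_geometry()
  s <- sinusoid_state(g)
  s$n_alive[] <- 0L  # all cells dead: conservative species
  inlet_total <- 0
  dt <- 65 * g$dt_sub_min
  for (i in 1:10) {
    s <- propagate_step(s, 100, dt)
    inlet_total <- inlet_total + 100 * g$v_bulk_L * 65
  }
  for (i in 1:5) s <- propagate_step(s, 0, dt)
  residual <- sum(s$bulk["APAP", ]) * g$v_bulk_L
  expect_lt(abs(s$outlet[["APAP"]] + residual - inlet_total) /
              inlet_total, 1e-6)
  expect_equal(s$E, 0)
})

test_that("propagate_step keeps mass balance and a sensible profile", {
  g <- test_geometry()
  s <- sinusoid_state(g, zone = zone_multiplier((1:16 - 0.5) / 16))
  dt <- 65 * g$dt_sub_min
  for (i in 1:30) s <- propagate_step(s, 1500, dt)  # no warning = balance
  # concentration decreases monotonically from portal to central vein
  expect_true(all(diff(s$bulk["APAP", ]) < 0))
  # elimination is positive and E non-decreasing
  expect_gt(elimination_rate(s, dt), 0)
  e_before <- s$E
  s <- propagate_step(s, 1500, dt)
  expect_gte(s$E, e_before)
  # center of mass of a pulse advances at U_x: after the inlet is shut
  # off, what remains drains with the flow
  expect_error(propagate_step(s, -5, dt), "negative")
})

test_that("elimination stops when the cells are gone", {
  g <- test_geometry()
  s <- sinusoid_state(g)
  dt <- 65 * g$dt_sub_min
  for (i in 1:10) s <- propagate_step(s, 1000, dt)
  r_alive <- elimination_rate(s, dt)
  s$n_alive[] <- 0L
  s <- propagate_step(s, 1000, dt)
  expect_gt(r_alive, 0)
  expect_equal(elimination_rate(s, dt), 0)
})
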