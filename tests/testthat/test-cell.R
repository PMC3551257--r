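test_that("reaction rates match an independent rate-law oracle", {
  set.seed(11)
  p <- enzyme_profile()
  for (i in 1:25) {
    s <- random_state(scale = 10^runif(1, 0, 4))
    zf <- runif(1, 0.5, 1.5)
    v <- reaction_rates(s, p, zf)
    expect_equal(as.numeric(v), as.numeric(oracle_rates(s, p, zf)),
                 tolerance = 1e-12)
  }
})

test_that("rates obey the limiting behaviours of the laws", {
  p <- enzyme_profile()
  zero <- cell_initial_state(p); zero[] <- 0
  # no substrate, no flux — except glutathione synthesis, a zero-order
  # lumped flux from precursors outside the modeled species set
  v_zero <- reaction_rates(zero, p)
  expect_true(all(v_zero[setdiff(names(v_zero), "gss")] == 0))
  expect_equal(v_zero[["gss"]], p[["vmax_gss"]])

  # saturation: summed NAPQI formation at APAP >> Km approaches
  # zone * Vmax_CYP3A4 + Vmax_CYP2E1 + Vmax_CYP_minor
  s <- zero; s[["APAP_cyt"]] <- 1e9
  v <- reaction_rates(s, p, zone_factor = 1.3)
  expect_equal(v[["cyp3a4"]] + v[["cyp2e1"]] + v[["cyp_minor"]],
               1.3 * p[["vmax_cyp3a4"]] + p[["vmax_cyp2e1"]] +
                 p[["vmax_cyp_minor"]],
               tolerance = 1e-5)

  # half saturation of UGT at its Km
  s2 <- zero; s2[["APAP_cyt"]] <- p[["km_ugt"]]
  expect_equal(reaction_rates(s2, p)[["ugt"]], p[["vmax_ugt"]] / 2)

  expect_error(reaction_rates(zero - 1, p), "negative")
  expect_error(reaction_rates(zero, p, zone_factor = 0), "zone_factor")
})

test_that("Michaelis-Menten fluxes are monotone in their substrate", {
  p <- enzyme_profile()
  grid <- c(0, 1, 10, 100, 1000, 1e4, 1e5)
  for (sp in c("APAP_cyt", "NAPQI", "H2O2", "GSSG")) {
    rates <- sapply(grid, function(x) {
      s <- cell_initial_state(p); s[[sp]] <- x
      reaction_rates(s, p)
    })
    mono <- apply(rates, 1, function(r) all(diff(r) >= -1e-12))
    # reactions consuming sp must be non-decreasing in it
    consuming <- build_network()$N[sp, ] < 0
    expect_true(all(mono[consuming]))
  }
})

test_that("cell RHS is N.v, zero for dead cells, single-reaction states", {
  p <- enzyme_profile()
  net <- build_network()
  s <- random_state()
  v <- reaction_rates(s, p, 1)
  expect_equal(as.numeric(cell_rhs(s, p, 1)),
               as.numeric(net$N %*% v), tolerance = 1e-12)

  expect_true(all(cell_rhs(s, p, alive = FALSE) == 0))

  # only GSSG present: the only active flux is GSR, dGSH/dt = +2 v_gsr
  s0 <- cell_initial_state(p); s0[] <- 0; s0[["GSSG"]] <- 50
  v0 <- reaction_rates(s0, p)
  expect_equal(sum(v0[setdiff(names(v0), c("gsr", "gss"))] != 0), 0)
  d <- cell_rhs(s0, p)
  expect_equal(d[["GSH"]], 2 * v0[["gsr"]] + v0[["gss"]])
})

test_that("a closed cell conserves the APAP moiety over 1000 min", {
  p <- enzyme_profile(vmax_uptake = 0, p_apap = 0, p_napqi = 0,
                      vmax_mrp2 = 0, vmax_mrp34 = 0)
  c0 <- cell_initial_state(p)
  c0[["APAP_cyt"]] <- 2000
  tr <- simulate_cell(c0, p, 0, 1000, out_dt = 50, ext_scale = 1)
  m <- apap_moiety()
  tot <- tr$states %*% m
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  # non-negativity within solver tolerance
  expect_gt(min(tr$states), -1e-4)
})

test_that("basal state is a fixed point and trajectories stay put", {
  p <- enzyme_profile()
  c0 <- cell_initial_state(p)
  expect_equal(max(abs(cell_rhs(c0, p))), 0)
  tr <- simulate_cell(c0, p, 0, 200, out_dt = 50)
  expect_lt(max(abs(sweep(tr$states, 2, c0))), 1e-6)
})

test_that("compiled trajectory agrees with an lsoda reference solve", {
  p <- enzyme_profile()
  c0 <- cell_initial_state(p)
  exposure <- 3000
  rhs_r <- function(t, y, parms) {
    y[["APAP_ext"]] <- exposure
    d <- cell_rhs(y, p, ext_scale = 1e-3, clamp_apap_ext = TRUE)
    list(as.numeric(d))
  }
  y0 <- c0; y0[["APAP_ext"]] <- exposure
  ref <- deSolve::lsoda(y0, seq(0, 240, by = 60), rhs_r, NULL,
                        rtol = 1e-9, atol = 1e-9)
  tr <- simulate_cell(c0, p, exposure, 240, out_dt = 60, rtol = 1e-8,
                      atol = 1e-8)
  for (sp in c("APAP_cyt", "NAPQI_P", "GSH", "H2O2"))
    expect_equal(tr$states[, sp], unname(ref[, sp]), tolerance = 1e-4)
})

test_that("trajectories are dose-linear in the sub-Km regime", {
  # with every Michaelis-Menten flux far below saturation, zero-order
  # and glutathione-turnover fluxes disabled, and the GST glutathione
  # term saturated, the dynamics are a linear ODE: halving the exposure
  # and the initial state halves the whole trajectory
  p <- enzyme_profile(k_ros = 0, vmax_gss = 0, vmax_ggt = 0,
                      km_gst_gsh = 1)
  c0 <- setNames(numeric(17), hepasim:::.hepasim_species())
  c0[["GSH"]] <- 3000
  c1 <- c0; c1[["GSH"]] <- 1500
  tr1 <- simulate_cell(c0, p, 2, 30, out_dt = 10, rtol = 1e-8,
                       atol = 1e-8)
  tr2 <- simulate_cell(c1, p, 1, 30, out_dt = 10, rtol = 1e-8,
                       atol = 1e-8)
  i <- nrow(tr1$states)
  for (sp in c("APAPG", "APAPS", "NAPQI", "APAP_cyt"))
    expect_equal(tr2$states[i, sp], tr1$states[i, sp] / 2,
                 tolerance = 5e-3)  # first-order Km correction remains
})

test_that("RHS is consistent with finite differences of the rates", {
  p <- enzyme_profile()
  net <- build_network()
  s <- random_state()
  h <- 1e-4
  for (sp in c("APAP_cyt", "GSH")) {
    sp_idx <- which(net$species == sp)
    s1 <- s; s1[[sp]] <- s[[sp]] + h
    num <- (cell_rhs(s1, p) - cell_rhs(s, p)) / h
    vjac <- (reaction_rates(s1, p) - reaction_rates(s, p)) / h
    expect_equal(as.numeric(num), as.numeric(net$N %*% vjac),
                 tolerance = 1e-6)
  }
})
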